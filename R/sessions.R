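#' Segment one chat's messages into consultations by an inactivity gap
#'
#' Messages are sorted by timestamp and partitioned greedily: a new
#' consultation starts whenever the gap from the previous message is at
#' least `gap_hours` (a gap of exactly the threshold starts a new
#' consultation). Concatenating the returned consultations restores the
#' time-sorted input.
#'
#' @param messages Data frame with columns `chat_id`, `sender`, `sent_at`
#'   (POSIXct), `text`, all sharing one `chat_id`.
#' @param gap_hours Inactivity threshold in hours (default 6).
#' @return List of consultations; each is a list with `chat_id`, `messages`
#'   (data frame), `start_at`, `end_at`, `n_chatter`, `n_counselor`,
#'   `n_total`.
#' @export
segment_sessions <- function(messages, gap_hours = 6) {
  if (nrow(messages) == 0L) return(list())
  if (length(unique(messages$chat_id)) > 1L)
    stop("`messages` must contain a single chat_id", call. = FALSE)
  messages <- messages[order(messages$sent_at), , drop = FALSE]
  sess <- cumsum(c(1, diff(as.numeric(messages$sent_at)) >= gap_hours * 3600))
  lapply(split(messages, sess), function(m) {
    list(chat_id = m$chat_id[1L], messages = m,
         start_at = m$sent_at[1L], end_at = m$sent_at[nrow(m)],
         n_chatter = sum(m$sender == "chatter"),
         n_counselor = sum(m$sender == "counselor"),
         n_total = nrow(m))
  })
}

# Vectorized sessionization over all chats: returns `messages` sorted by
# (chat_id, sent_at) with an integer `consultation` column (1-based per chat).
sessionize <- function(messages, gap_hours = 6) {
  o <- order(messages$chat_id, messages$sent_at)
  m <- messages[o, , drop = FALSE]
  tt <- as.numeric(m$sent_at)
  new_chat <- c(TRUE, m$chat_id[-1L] != m$chat_id[-nrow(m)])
  brk <- new_chat | c(TRUE, diff(tt) >= gap_hours * 3600)
  sid <- cumsum(brk)
  first_of_chat <- sid[new_chat]
  m$consultation <- sid - rep.int(first_of_chat,
                                  diff(c(which(new_chat), nrow(m) + 1L))) + 1L
  rownames(m) <- NULL
  m
}

#' Does a consultation qualify as a counseling session?
#'
#' A consultation qualifies when it contains at least `min_counselor`
#' counselor messages and at least `min_total` messages overall.
#'
#' @param x A consultation from [segment_sessions()], or a data frame with
#'   columns `n_counselor` and `n_total` (vectorized).
#' @param min_counselor,min_total Qualification thresholds (defaults 3 / 10).
#' @return Logical (vector when `x` is a data frame).
#' @export
qualifies <- function(x, min_counselor = 3L, min_total = 10L) {
  x$n_counselor >= min_counselor & x$n_total >= min_total
}

#' Build per-chatter episodes: index consultation, counts and outcome label
#'
#' Sessionizes every chat, finds the first qualifying consultation (the
#' "index"), and labels the recontact outcome: `TRUE` iff any later
#' consultation containing at least one chatter message starts within
#' `window_days` (inclusive) of the index consultation's end. Contacts
#' merged into the index by the gap rule never count as recontact. Chatters
#' with no qualifying consultation are excluded (their count is kept in the
#' `n_excluded` attribute).
#'
#' @param messages Message data frame (any number of chats).
#' @inheritParams segment_sessions
#' @inheritParams qualifies
#' @param window_days Outcome window in days, inclusive (default 188).
#' @return Data frame with one row per chatter holding a qualifying index
#'   consultation: `chat_id`, `index_consultation`, `index_start`,
#'   `index_end`, `n_chatter`, `n_counselor`, `n_total`, `wc_chatter`,
#'   `wc_counselor`, `word_count`, `start_hour`, `label`. Attribute
#'   `n_excluded` counts chatters without a qualifying consultation.
#' @export
build_episodes <- function(messages, gap_hours = 6, min_counselor = 3L,
                           min_total = 10L, window_days = 188) {
  m <- sessionize(messages, gap_hours)
  wc <- lengths(strsplit(m$text, "[[:space:]]+"))
  key <- paste(m$chat_id, m$consultation, sep = "\r")
  ord_keys <- unique(key)  # already in (chat, consultation) order
  f <- factor(key, levels = ord_keys)
  cons <- data.frame(
    chat_id = m$chat_id[!duplicated(key)],
    consultation = m$consultation[!duplicated(key)],
    start_at = as.POSIXct(tapply(as.numeric(m$sent_at), f, min),
                          origin = "1970-01-01", tz = "UTC"),
    end_at = as.POSIXct(tapply(as.numeric(m$sent_at), f, max),
                        origin = "1970-01-01", tz = "UTC"),
    n_chatter = as.integer(tapply(m$sender == "chatter", f, sum)),
    n_counselor = as.integer(tapply(m$sender == "counselor", f, sum)),
    wc_chatter = as.integer(tapply(wc * (m$sender == "chatter"), f, sum)),
    wc_counselor = as.integer(tapply(wc * (m$sender == "counselor"), f, sum)),
    stringsAsFactors = FALSE
  )
  cons$n_total <- cons$n_chatter + cons$n_counselor
  cons$qual <- qualifies(cons, min_counselor, min_total)

  out <- lapply(split(cons, cons$chat_id), function(cc) {
    idx <- which(cc$qual)[1L]
    if (is.na(idx)) return(NULL)
    later <- cc[-seq_len(idx), , drop = FALSE]
    lab <- label_from_consultations(later, cc$end_at[idx], window_days)
    data.frame(
      chat_id = cc$chat_id[1L], index_consultation = cc$consultation[idx],
      index_start = cc$start_at[idx], index_end = cc$end_at[idx],
      n_chatter = cc$n_chatter[idx], n_counselor = cc$n_counselor[idx],
      n_total = cc$n_total[idx],
      wc_chatter = cc$wc_chatter[idx], wc_counselor = cc$wc_counselor[idx],
      word_count = cc$wc_chatter[idx] + cc$wc_counselor[idx],
      start_hour = as.integer(format(cc$start_at[idx], "%H", tz = "UTC")),
      label = lab, stringsAsFactors = FALSE)
  })
  keep <- !vapply(out, is.null, TRUE)
  res <- do.call(rbind, out[keep])
  rownames(res) <- NULL
  attr(res, "n_excluded") <- sum(!keep)
  attr(res, "gap_hours") <- gap_hours
  res
}

label_from_consultations <- function(later, index_end, window_days) {
  if (nrow(later) == 0L) return(FALSE)
  any(later$n_chatter >= 1L &
        as.numeric(later$start_at) - as.numeric(index_end) <=
        window_days * 86400)
}

#' Label the recontact outcome for one chatter's episodes
#'
#' @param episodes List with elements `consultations` (a list as returned by
#'   [segment_sessions()]) and `index` (position of the index consultation).
#' @param window_days Outcome window in days, inclusive.
#' @return Logical label.
#' @export
label_outcome <- function(episodes, window_days = 188) {
  idx <- episodes$index
  cons <- episodes$consultations
  if (is.null(idx) || is.na(idx))
    stop("no index consultation: label undefined", call. = FALSE)
  if (idx >= length(cons)) return(FALSE)
  end0 <- as.numeric(cons[[idx]]$end_at)
  any(vapply(cons[(idx + 1L):length(cons)], function(cn)
    cn$n_chatter >= 1L &&
      as.numeric(cn$start_at) - end0 <= window_days * 86400, TRUE))
}

#' Time-based train/test split
#'
#' Records whose index consultation starts before `cutoff` form the train
#' set; all others (including records starting exactly at the cutoff) form
#' the test set.
#'
#' @param records Episode table from [build_episodes()].
#' @param cutoff POSIXct timestamp (or string parseable as UTC date-time).
#' @return `records` with an added `split` factor (`"train"`/`"test"`).
#' @export
time_split <- function(records, cutoff) {
  if (is.character(cutoff))
    cutoff <- as.POSIXct(cutoff, tz = "UTC")
  records$split <- factor(ifelse(records$index_start < cutoff,
                                 "train", "test"),
                          levels = c("train", "test"))
  if (any(table(records$split) == 0L))
    warning("time_split produced an empty side", call. = FALSE)
  records
}

#' Sensitivity of a score to the outcome-window choice
#'
#' Relabels the corpus at each candidate outcome window and evaluates
#' `eval_fn` on the relabeled episode table, returning the per-window scores
#' and their standard deviation.
#'
#' @param messages Message data frame.
#' @param eval_fn Function taking the relabeled episode table and returning
#'   a single numeric score (e.g. a cross-validated AUROC).
#' @param windows Outcome windows in days (default 150 to 210 by 10).
#' @inheritParams build_episodes
#' @return Data frame (`window_days`, `score`) with attribute `sd`.
#' @export
outcome_window_sensitivity <- function(messages, eval_fn,
                                       windows = seq(150, 210, by = 10),
                                       gap_hours = 6, min_counselor = 3L,
                                       min_total = 10L) {
  if (length(windows) == 0L)
    stop("`windows` must be non-empty", call. = FALSE)
  scores <- vapply(windows, function(w) {
    rec <- build_episodes(messages, gap_hours, min_counselor, min_total,
                          window_days = w)
    as.numeric(eval_fn(rec))
  }, 0)
  out <- data.frame(window_days = windows, score = scores)
  attr(out, "sd") <- if (length(scores) > 1L) sd(scores) else 0
  out
}

#' Extract per-speaker documents of the index consultations
#'
#' Concatenates, per chatter and channel, the raw text of all messages in
#' the index consultation, yielding the two documents per chat that the
#' anonymizer and vectorizer operate on.
#'
#' @param messages Message data frame.
#' @param records Episode table from [build_episodes()] (its `gap_hours`
#'   attribute is reused).
#' @return Data frame with columns `chat_id`, `channel`, `text`; two rows
#'   per chatter (a channel with no messages yields an empty string).
#' @export
collect_speaker_docs <- function(messages, records) {
  gap_hours <- attr(records, "gap_hours") %||% 6
  m <- sessionize(messages[messages$chat_id %in% records$chat_id, ,
                           drop = FALSE], gap_hours)
  idx <- records$index_consultation[match(m$chat_id, records$chat_id)]
  m <- m[m$consultation == idx, , drop = FALSE]
  grid <- expand.grid(chat_id = records$chat_id,
                      channel = c("chatter", "counselor"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(m$chat_id, m$sender)
  txt <- vapply(split(m$text, key), paste, "", collapse = " ")
  grid$text <- unname(txt[paste(grid$chat_id, grid$channel)])
  grid$text[is.na(grid$text)] <- ""
  grid <- grid[order(grid$chat_id, grid$channel), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}
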