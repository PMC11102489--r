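#' Generate a synthetic chat corpus with planted outcome structure
#'
#' Emits one first consultation per chatter (message counts, word counts and
#' start times drawn from the calibrated laws in the configuration), plants
#' topic/word signal tied to a latent logistic recontact model, and appends a
#' later consultation for chatters whose sampled recontact label is positive.
#' The output is a timestamped two-party message stream plus a ground-truth
#' table for parameter-recovery tests. Fully deterministic given the
#' configuration (including its seed); the caller's RNG state is untouched.
#'
#' Message texts are space-joined word stems drawn from the background
#' lexicon plus the chatter's active topic lexicons. Each active chatter
#' topic is mirrored into the counselor's messages with probability
#' `mirror_prob`; redirection stems are emitted only by counselors.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_corpus` with elements `messages` (data frame:
#'   `chat_id`, `sender`, `sent_at` POSIXct UTC, `text`), `truth` (one row
#'   per chatter: latents, true probability, label, delay), and `intercept`
#'   (the calibrated logistic intercept).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cal <- calibrate_counts(config)
  b0 <- calibrate_intercept(config)
  n <- config$n_chatters
  lex <- config$topic_lexicons
  tp <- config$topic_priors

  with_seed(config$seed, {
    ## ---- latent traits -------------------------------------------------
    age <- sample(config$age_dist$values, n, TRUE, config$age_dist$probs)
    female <- runif(n) < config$p_female
    sh <- runif(n) < tp$self_harm
    su <- runif(n) < tp$suicide
    wk <- runif(n) < tp$work
    rd <- runif(n) < tp$redirection
    hour <- sample(0:23, n, TRUE, config$start_time_dist)
    night <- hour %in% config$night_hours
    tod <- runif(n) < ifelse(night, tp$time_of_day["night"], tp$time_of_day["day"])
    emo <- runif(n) < ifelse(female, tp$emotion_adjectives["female"],
                             tp$emotion_adjectives["male"])
    say_age <- runif(n) < tp$numbers

    eff <- config$effect_log_odds
    lp <- b0 +
      (age <= 15) * eff["young"] +
      ifelse(female, eff["female"], eff["male"]) +
      sh * eff["self_harm"] + su * eff["suicide"] +
      night * eff["night"] + wk * eff["work"] + rd * eff["redirection"]
    p_true <- plogis(unname(lp))
    label <- runif(n) < p_true
    delay <- rep(NA_real_, n)
    delay[label] <- sample_delay(sum(label), config$recontact_delay)

    ## ---- qualifying message counts (rejection-sampled truncation) ------
    nc <- rnbinom(n, size = cal$size_chatter, mu = cal$mu_chatter)
    nk <- rnbinom(n, size = cal$size_counselor, mu = cal$mu_counselor)
    bad <- which(nk < 3L | nc + nk < 10L)
    while (length(bad)) {
      nc[bad] <- rnbinom(length(bad), size = cal$size_chatter,
                         mu = cal$mu_chatter)
      nk[bad] <- rnbinom(length(bad), size = cal$size_counselor,
                         mu = cal$mu_counselor)
      bad <- bad[nk[bad] < 3L | nc[bad] + nk[bad] < 10L]
    }
    ntot <- nc + nk
    words <- pmin(ntot + rnbinom(n, size = cal$words_extra_size,
                                 mu = cal$words_extra_mean),
                  config$total_words_dist$cap)

    ## ---- start times ---------------------------------------------------
    day0 <- as.numeric(as.POSIXct(paste(config$calendar[1], "00:00:00"),
                                  tz = "UTC"))
    day1 <- as.numeric(as.POSIXct(paste(config$calendar[2], "00:00:00"),
                                  tz = "UTC"))
    start <- day0 + floor(runif(n) * ((day1 - day0) / 86400)) * 86400 +
      hour * 3600 + floor(runif(n, 0, 3600))

    mirror_topics <- c("self_harm", "suicide", "work", "time_of_day",
                       "emotion_adjectives", "numbers")

    ## ---- compose chats -------------------------------------------------
    chat_ids <- sprintf("c%06d", seq_len(n))
    out_id <- out_sender <- out_text <- vector("list", n)
    out_time <- vector("list", n)
    for (i in seq_len(n)) {
      active <- list()
      if (sh[i]) active$self_harm <- lex$self_harm
      if (su[i]) active$suicide <- lex$suicide
      if (wk[i]) active$work <- lex$work
      if (tod[i]) active$time_of_day <- lex$time_of_day
      if (emo[i]) active$emotion_adjectives <- lex$emotion_adjectives
      if (say_age[i]) active$numbers <- rep(as.character(age[i]), 3L)

      roles <- sample(rep(c("chatter", "counselor"), c(nc[i], nk[i])))
      wpm <- rep(1L, ntot[i])
      extra <- words[i] - ntot[i]
      if (extra > 0L)
        wpm <- wpm + tabulate(sample.int(ntot[i], extra, replace = TRUE),
                              nbins = ntot[i])
      is_ch <- roles == "chatter"
      w_ch <- sum(wpm[is_ch])
      w_co <- sum(wpm[!is_ch])

      pool_ch <- unlist(active, use.names = FALSE)
      ch_tokens <- draw_tokens(w_ch, pool_ch, lex$background, 0.30)

      mirrored <- intersect(names(active), mirror_topics)
      mirrored <- mirrored[runif(length(mirrored)) < config$mirror_prob]
      pool_co <- c(if (rd[i]) lex$redirection,
                   unlist(active[mirrored], use.names = FALSE))
      co_tokens <- draw_tokens(w_co, pool_co, lex$background, 0.25)
      if (length(mirrored) && w_co > 0L) {
        # guarantee at least one stem of every mirrored topic
        inject <- vapply(active[mirrored], function(v) sample(v, 1L), "")
        inject <- inject[seq_len(min(length(inject), w_co))]
        co_tokens[sample.int(w_co, length(inject))] <- inject
      }

      msg_of_word <- rep.int(seq_len(ntot[i]), wpm)
      texts <- character(ntot[i])
      tok <- character(words[i])
      tok[is_ch[msg_of_word]] <- ch_tokens
      tok[!is_ch[msg_of_word]] <- co_tokens
      texts <- vapply(split(tok, msg_of_word), paste, "", collapse = " ",
                      USE.NAMES = FALSE)

      times <- start[i] + c(0, cumsum(runif(ntot[i] - 1L, 30, 1200)))

      if (label[i]) {
        # recontact: a short later consultation; delay is measured from the
        # end of the first consultation and always exceeds the 6-h gap
        r_start <- times[ntot[i]] + delay[i] * 86400
        r_roles <- c("chatter", "chatter", "counselor", "chatter")
        r_texts <- vapply(seq_along(r_roles), function(j)
          paste(sample(lex$background, sample(3:8, 1L), TRUE),
                collapse = " "), "")
        roles <- c(roles, r_roles)
        texts <- c(texts, r_texts)
        times <- c(times, r_start + c(0, cumsum(runif(3, 60, 300))))
      }
      out_id[[i]] <- rep.int(chat_ids[i], length(roles))
      out_sender[[i]] <- roles
      out_time[[i]] <- times
      out_text[[i]] <- texts
    }

    messages <- data.frame(
      chat_id = unlist(out_id, use.names = FALSE),
      sender = unlist(out_sender, use.names = FALSE),
      sent_at = as.POSIXct(unlist(out_time, use.names = FALSE),
                           origin = "1970-01-01", tz = "UTC"),
      text = unlist(out_text, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      chat_id = chat_ids, age = age, female = female,
      self_harm = sh, suicide = su, work = wk, redirection = rd,
      time_of_day = tod, emotion_adjectives = emo, says_age = say_age,
      start_hour = hour, night = night,
      p_true = p_true, label = label, delay_days = delay,
      stringsAsFactors = FALSE
    )

    if (config$emit_nonqualifying) {
      nq <- emit_nonqualifying(config, cal, day0, day1)
      messages <- rbind(messages, nq$messages)
      messages <- messages[order(messages$chat_id), ]
      truth$qualifies <- TRUE
      nq$truth$qualifies <- FALSE
      truth <- rbind(truth, nq$truth)
    }

    structure(list(messages = messages, truth = truth, intercept = b0),
              class = "synth_corpus")
  })
}

# Draw n tokens: with probability p_topic from the (non-empty) topic pool,
# otherwise from the background lexicon.
draw_tokens <- function(n, pool, background, p_topic) {
  if (n == 0L) return(character())
  out <- sample(background, n, TRUE)
  if (length(pool)) {
    hit <- runif(n) < p_topic
    k <- sum(hit)
    if (k) out[hit] <- pool[sample.int(length(pool), k, TRUE)]
  }
  out
}

# Delay mixture: uniform within the first week w.p. p_week, else an
# exponential tail truncated to (week_max, max_days].
sample_delay <- function(n, rd) {
  early <- runif(n) < rd$p_week
  d <- numeric(n)
  d[early] <- runif(sum(early), rd$min_days, rd$week_max)
  k <- sum(!early)
  if (k) {
    u <- runif(k)
    span <- rd$max_days - rd$week_max
    # inverse-cdf sampling of Exp(tail_mean) truncated to [0, span]
    cmax <- 1 - exp(-span / rd$tail_mean)
    d[!early] <- rd$week_max - rd$tail_mean * log(1 - u * cmax)
  }
  d
}

# Contacts that never reach a qualifying consultation (optional emulation of
# the study's exclusion share).
emit_nonqualifying <- function(config, cal, day0, day1) {
  r <- config$nonqualifying_rate
  m <- round(config$n_chatters * r / (1 - r))
  lex <- config$topic_lexicons
  ids <- sprintf("x%06d", seq_len(m))
  nc <- pmin(rnbinom(m, size = cal$size_chatter, mu = 2), 6L)
  nk <- sample(0:2, m, TRUE)
  over <- which(nc + nk >= 10L | nk >= 3L)
  nc[over] <- pmin(nc[over], 9L - nk[over])
  hour <- sample(0:23, m, TRUE, config$start_time_dist)
  start <- day0 + floor(runif(m) * ((day1 - day0) / 86400)) * 86400 +
    hour * 3600
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    ntot <- nc[i] + nk[i]
    if (ntot == 0L) ntot <- nc[i] <- 1L
    roles <- sample(rep(c("chatter", "counselor"), c(nc[i], nk[i])))
    texts <- vapply(seq_len(ntot), function(j)
      paste(sample(lex$background, sample(2:6, 1L), TRUE), collapse = " "), "")
    rows[[i]] <- data.frame(
      chat_id = ids[i], sender = roles,
      sent_at = as.POSIXct(start[i] + c(0, cumsum(runif(ntot - 1L, 30, 1200))),
                           origin = "1970-01-01", tz = "UTC"),
      text = texts, stringsAsFactors = FALSE)
  }
  truth <- data.frame(
    chat_id = ids, age = NA_integer_, female = NA, self_harm = NA,
    suicide = NA, work = NA, redirection = NA, time_of_day = NA,
    emotion_adjectives = NA, says_age = NA, start_hour = hour,
    night = hour %in% config$night_hours, p_true = NA_real_, label = NA,
    delay_days = NA_real_, stringsAsFactors = FALSE)
  list(messages = do.call(rbind, rows), truth = truth)
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat(sprintf("<synth_corpus> %d messages, %d chatters\n",
              nrow(x$messages), nrow(x$truth)))
  invisible(x)
}

#' Read and write message streams as JSONL or CSV
#'
#' One record per message with keys `chat_id`, `sender`, `sent_at`
#' (ISO-8601, UTC) and `text`. The ground-truth companion table uses one
#' record per chatter keyed by `chat_id`.
#'
#' @param messages Data frame of messages as produced by [generate_corpus()].
#' @param path Output/input file path; format chosen by extension
#'   (`.jsonl` or `.csv`).
#' @return `write_messages()` returns `path` invisibly; `read_messages()`
#'   returns the messages data frame with `sent_at` parsed to POSIXct.
#' @export
write_messages <- function(messages, path) {
  df <- messages
  df$sent_at <- format(df$sent_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (grepl("\\.csv$", path)) {
    write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    jsonlite::stream_out(df, con, verbose = FALSE)
  }
  invisible(path)
}

#' @rdname write_messages
#' @export
read_messages <- function(path) {
  df <- if (grepl("\\.csv$", path)) {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    con <- file(path, "r")
    on.exit(close(con))
    jsonlite::stream_in(con, verbose = FALSE)
  }
  df$sent_at <- as.POSIXct(df$sent_at, format = "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC")
  df
}

#' @rdname write_messages
#' @param truth Ground-truth data frame from [generate_corpus()].
#' @export
write_truth <- function(truth, path) {
  if (grepl("\\.csv$", path)) {
    write.csv(truth, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    jsonlite::stream_out(truth, con, verbose = FALSE)
  }
  invisible(path)
}
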