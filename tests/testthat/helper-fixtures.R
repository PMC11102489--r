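# Shared fixtures and independent oracles used across the suite.

# Toy message stream: one chat, messages at the given offsets (in hours).
msg_stream <- function(hours, senders = NULL, chat = "a",
                       origin = "2022-01-01 12:00:00") {
  n <- length(hours)
  if (is.null(senders))
    senders <- rep_len(c("chatter", "counselor"), n)
  data.frame(
    chat_id = rep(chat, n),
    sender = senders,
    sent_at = as.POSIXct(origin, tz = "UTC") + hours * 3600,
    text = if (n) paste("wort", seq_len(n)) else character(0),
    stringsAsFactors = FALSE
  )
}

# Brute-force sessionizer: linear scan inserting a boundary at every gap >=
# the threshold; returns the consultation id of each (sorted) message.
brute_partition <- function(hours, gap_hours = 6) {
  hours <- sort(hours)
  id <- integer(length(hours))
  cur <- 1L
  for (i in seq_along(hours)) {
    if (i > 1L && hours[i] - hours[i - 1L] >= gap_hours) cur <- cur + 1L
    id[i] <- cur
  }
  id
}

# Brute-force AUROC: all positive/negative pairs, ties count one half.
brute_auroc <- function(labels, scores) {
  y <- as.logical(labels)
  pos <- scores[y]
  neg <- scores[!y]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Small anonymized corpus built directly from stem lists.
stem_corpus <- function(chat_stems) {
  rows <- list()
  for (chat in names(chat_stems)) {
    for (ch in c("chatter", "counselor")) {
      rows[[length(rows) + 1L]] <- data.frame(
        chat_id = chat, channel = ch, stringsAsFactors = FALSE)
      rows[[length(rows)]]$stems <- list(chat_stems[[chat]][[ch]] %||%
                                           character())
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Separable toy document corpus: positives carry a marker stem.
separable_corpus <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("s%03d", seq_len(n))
    lab <- rep(c(TRUE, FALSE), length.out = n)
    filler <- c("eins", "zwei", "drei", "vier")
    rows <- lapply(seq_len(n), function(i) {
      ch <- c(sample(filler, 6, TRUE), if (lab[i]) c("marker", "marker"))
      co <- sample(filler, 5, TRUE)
      out <- data.frame(chat_id = ids[i],
                        channel = c("chatter", "counselor"),
                        stringsAsFactors = FALSE)
      out$stems <- list(ch, co)
      out
    })
    list(docs = do.call(rbind, rows), labels = setNames(lab, ids))
  })
}

# Cheap logistic pipelines over fixed feature columns, for the paired
# classifier comparisons.
acc_glm_pipeline <- function(X, cols) {
  list(
    fit = function(ids, labels) {
      df <- data.frame(y = as.numeric(labels[ids]),
                       X[ids, cols, drop = FALSE])
      suppressWarnings(glm(y ~ ., binomial, df))
    },
    predict = function(model, ids) {
      suppressWarnings(
        predict(model, data.frame(X[ids, cols, drop = FALSE]),
                type = "response"))
    })
}

# Baseline-class booster pipeline over fixed metadata-like features; two
# instances differing only in training seed form the null comparison.
acc_baseline_pipeline <- function(X, seed) {
  list(
    fit = function(ids, labels) {
      rechat:::fit_booster(X[ids, , drop = FALSE], labels[ids],
                           booster_params(eta = 0.1, gamma = 0,
                                          max_depth = 3,
                                          min_child_weight = 5,
                                          subsample = 0.6,
                                          colsample_bytree = 0.8),
                           40L, seed)
    },
    predict = function(model, ids) {
      predict(model, xgboost::xgb.DMatrix(X[ids, , drop = FALSE]))
    })
}

# A small synthetic corpus shared by the heavier unit tests.
small_corpus <- local({
  cache <- NULL
  function(n = 600, seed = 99) {
    if (is.null(cache))
      cache <<- generate_corpus(synth_config(n_chatters = n, seed = seed))
    cache
  }
})
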