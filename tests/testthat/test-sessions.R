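test_that("sessionization splits at the inactivity gap, inclusively", {
  expect_identical(segment_sessions(msg_stream(numeric(0))), list())

  s <- segment_sessions(msg_stream(c(0, 1, 2, 9)))
  expect_length(s, 2L)
  expect_equal(s[[1]]$n_total, 3L)
  expect_equal(s[[2]]$n_total, 1L)

  # a gap of exactly the threshold starts a new consultation
  s6 <- segment_sessions(msg_stream(c(0, 6)))
  expect_length(s6, 2L)
  s5 <- segment_sessions(msg_stream(c(0, 5.99)))
  expect_length(s5, 1L)

  mixed <- rbind(msg_stream(c(0, 1), chat = "a"),
                 msg_stream(c(0, 1), chat = "b"))
  expect_error(segment_sessions(mixed), "single chat_id")
})

test_that("sessionizer agrees with a brute-force gap partition on random streams", {
  withr::with_seed(42, {
    for (i in 1:150) {
      n <- sample(1:50, 1)
      hours <- sort(runif(n, 0, 100))
      m <- msg_stream(hours)
      got <- segment_sessions(m)
      want <- brute_partition(hours)
      expect_equal(length(got), max(want))
      expect_equal(rep.int(seq_along(got),
                           vapply(got, `[[`, 0L, "n_total")), want)
      # conservation: concatenating consultations restores the input
      expect_equal(sum(vapply(got, `[[`, 0L, "n_total")), n)
    }
  })
})

test_that("qualification needs 3 counselor messages and 10 in total", {
  mk <- function(nch, nco) list(n_counselor = nco, n_total = nch + nco)
  expect_true(qualifies(mk(7, 3)))
  expect_false(qualifies(mk(0, 0)))
  expect_false(qualifies(mk(20, 2)))  # counselor rule binds despite 22 total
  expect_false(qualifies(mk(6, 3)))
})

test_that("outcome labeling counts only genuinely new consultations", {
  # next consultation 10 days later -> recontact
  m <- rbind(msg_stream(0:10, senders = rep(c("counselor", "chatter"), c(4, 7))),
             msg_stream(10 + 240, senders = "chatter"))
  rec <- build_episodes(m)
  expect_true(rec$label)

  # nothing after the index -> no recontact
  m2 <- msg_stream(0:10, senders = rep(c("counselor", "chatter"), c(4, 7)))
  expect_false(build_episodes(m2)$label)

  # a follow-up 5 h after the last message merges into the index
  m3 <- rbind(m2, msg_stream(10 + 5, senders = "chatter"))
  rec3 <- build_episodes(m3)
  expect_false(rec3$label)
  expect_equal(rec3$n_total, 12L)

  # recontact outside the window does not count; inclusive day-188 boundary
  mk_delayed <- function(days) {
    idx <- msg_stream(0:10, senders = rep(c("counselor", "chatter"), c(4, 7)))
    rbind(idx, msg_stream(10 + days * 24, senders = "chatter"))
  }
  expect_true(build_episodes(mk_delayed(188))$label)
  expect_false(build_episodes(mk_delayed(188.5))$label)

  # a counselor-only later consultation is not a recontact by the chatter
  m4 <- rbind(m2, msg_stream(10 + 240, senders = "counselor"))
  expect_false(build_episodes(m4)$label)
})

test_that("label_outcome on explicit episodes matches the episode builder", {
  m <- rbind(msg_stream(0:10, senders = rep(c("counselor", "chatter"), c(4, 7))),
             msg_stream(10 + 100, senders = "chatter"))
  cons <- segment_sessions(m)
  ep <- list(consultations = cons, index = 1L)
  expect_true(label_outcome(ep))
  expect_error(label_outcome(list(consultations = cons, index = NA)),
               "index")
})

test_that("enlarging the outcome window never flips labels to negative", {
  corp <- small_corpus()
  prev <- NULL
  for (w in c(60, 120, 188, 250)) {
    rec <- build_episodes(corp$messages, window_days = w)
    if (!is.null(prev)) expect_true(all(rec$label >= prev))
    prev <- rec$label
  }
})

test_that("the time split is exhaustive, disjoint, and half-open at the cutoff", {
  corp <- small_corpus()
  rec <- build_episodes(corp$messages)
  cut <- as.POSIXct(quantile(as.numeric(rec$index_start), 0.79),
                    origin = "1970-01-01", tz = "UTC")
  sp <- time_split(rec, cut)
  expect_equal(sum(sp$split == "train") + sum(sp$split == "test"), nrow(rec))
  expect_equal(mean(sp$split == "test"), 0.21, tolerance = 0.01)

  exact <- rec[1, ]
  exact$index_start <- cut
  expect_equal(as.character(time_split(rbind(rec, exact), cut)$split[nrow(rec) + 1]),
               "test")

  expect_warning(time_split(rec, max(rec$index_start) + 1), "empty")
})

test_that("window sensitivity reports zero spread for constant scores", {
  corp <- generate_corpus(synth_config(n_chatters = 30, seed = 8))
  out <- outcome_window_sensitivity(corp$messages, function(rec) 0.7,
                                    windows = seq(150, 210, 10))
  expect_equal(attr(out, "sd"), 0)
  single <- outcome_window_sensitivity(corp$messages, function(rec)
    mean(rec$label), windows = 188)
  expect_equal(attr(single, "sd"), 0)
  expect_error(outcome_window_sensitivity(corp$messages, mean,
                                          windows = integer(0)),
               "non-empty")
})

test_that("window sensitivity is small when delays concentrate early", {
  corp <- small_corpus()
  out <- outcome_window_sensitivity(corp$messages, function(rec)
    mean(rec$label), windows = seq(150, 210, 10))
  expect_lt(attr(out, "sd"), 0.01)
  expect_true(all(diff(out$score) >= 0))  # monotone in the window
})

test_that("speaker documents cover both channels of every index consultation", {
  corp <- generate_corpus(synth_config(n_chatters = 25, seed = 13))
  rec <- build_episodes(corp$messages)
  docs <- collect_speaker_docs(corp$messages, rec)
  expect_equal(nrow(docs), 2L * nrow(rec))
  expect_setequal(unique(docs$channel), c("chatter", "counselor"))
  # word counts in the docs match the episode word counts
  wc <- vapply(strsplit(docs$text, "[[:space:]]+"),
               function(x) sum(nzchar(x)), 0L)
  got <- tapply(wc, docs$chat_id, sum)
  expect_equal(as.vector(got[rec$chat_id]), rec$word_count)
})
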