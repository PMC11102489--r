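test_that("intercept calibration solves the logit identity in closed-form cases", {
  cfg <- synth_config(n_chatters = 10, effect_log_odds = c(
    young = 0, female = 0, male = 0, self_harm = 0, suicide = 0,
    night = 0, work = 0, redirection = 0))
  expect_equal(calibrate_intercept(cfg), qlogis(0.431), tolerance = 1e-6)

  # symmetric gender effects around a balanced population, target 1/2
  cfg2 <- synth_config(n_chatters = 10, target_prevalence = 0.5,
                       p_female = 0.5, effect_log_odds = c(
                         young = 0, female = 0.7, male = -0.7,
                         self_harm = 0, suicide = 0, night = 0,
                         work = 0, redirection = 0))
  expect_equal(calibrate_intercept(cfg2), 0, tolerance = 1e-6)
})

test_that("calibrated intercept matches a Monte-Carlo grid-search oracle", {
  cfg <- synth_config(n_chatters = 10, seed = 3)
  b0 <- calibrate_intercept(cfg)
  # oracle: simulate the latents at large n and grid-search the intercept
  # that matches the target prevalence
  prev_at <- function(b) {
    withr::with_seed(2024, {
      n <- 50000
      ad <- cfg$age_dist
      age <- sample(ad$values, n, TRUE, ad$probs)
      female <- runif(n) < cfg$p_female
      sh <- runif(n) < cfg$topic_priors$self_harm
      su <- runif(n) < cfg$topic_priors$suicide
      wk <- runif(n) < cfg$topic_priors$work
      rd <- runif(n) < cfg$topic_priors$redirection
      hour <- sample(0:23, n, TRUE, cfg$start_time_dist)
      night <- hour %in% cfg$night_hours
      eff <- cfg$effect_log_odds
      lp <- b + (age <= 15) * eff["young"] +
        ifelse(female, eff["female"], eff["male"]) +
        sh * eff["self_harm"] + su * eff["suicide"] +
        night * eff["night"] + wk * eff["work"] + rd * eff["redirection"]
      mean(plogis(lp))
    })
  }
  grid <- seq(-3, 1, by = 0.01)
  oracle_b0 <- grid[which.min(abs(vapply(grid, prev_at, 0) - 0.431))]
  expect_lt(abs(b0 - oracle_b0), 0.05)
  expect_lt(abs(prev_at(b0) - 0.431), 5e-3)
})

test_that("count calibration reproduces the truncated target moments exactly", {
  cfg <- synth_config(n_chatters = 10)
  cal <- calibrate_counts(cfg)
  expect_equal(cal$moments$mean_chatter, 25.4, tolerance = 1e-3)
  expect_equal(cal$moments$mean_counselor, 17.7, tolerance = 1e-3)
  # truncation pushes the underlying means below the conditional targets
  expect_lt(cal$mu_chatter, 25.4)
  expect_lt(cal$mu_counselor, 17.7)
})

test_that("generated corpora are deterministic in the seed and qualify throughout", {
  cfg <- synth_config(n_chatters = 40, seed = 5)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a, b)
  c <- generate_corpus(synth_config(n_chatters = 40, seed = 6))
  expect_false(identical(a$messages$text, c$messages$text))

  rec <- build_episodes(a$messages)
  expect_equal(nrow(rec), 40L)
  expect_true(all(qualifies(rec)))
  # delay present iff label positive
  expect_identical(is.na(a$truth$delay_days), !a$truth$label)
  expect_true(all(a$truth$delay_days[a$truth$label] > 0.25))
})

test_that("generator moments and prevalence are near targets at moderate n", {
  corp <- small_corpus()
  rec <- build_episodes(corp$messages)
  n <- nrow(rec)
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(rec$n_chatter) - 25.4), 4 * se(rec$n_chatter))
  expect_lt(abs(mean(rec$n_counselor) - 17.7), 4 * se(rec$n_counselor))
  expect_lt(abs(mean(rec$word_count) - 456.4), 4 * se(rec$word_count))
  expect_lt(abs(mean(rec$label) - 0.431), 4 * se(rec$label))
  expect_lte(max(rec$word_count), 3340)
  # sessionized labels agree with the generator's ground truth
  tr <- corp$truth
  expect_identical(rec$label, tr$label[match(rec$chat_id, tr$chat_id)])
})

test_that("configuration validation rejects inconsistent setups", {
  expect_error(synth_config(n_chatters = 0), "positive")
  lex <- default_lexicons()
  lex$suicide <- c(lex$suicide, lex$self_harm[1])
  expect_error(synth_config(n_chatters = 5, topic_lexicons = lex),
               "disjoint")
  expect_error(synth_config(n_chatters = 5,
                            recontact_delay = list(p_week = 0.2,
                                                   min_days = 0.3,
                                                   week_max = 7,
                                                   tail_mean = 40,
                                                   max_days = 188)),
               "half its mass")
  expect_error(
    synth_config(n_chatters = 5,
                 chatter_msg_dist = list(mean = 10, sd = 1)),
    "over-dispersed")
})

test_that("recontact delays honour the early-week mass and the outcome window", {
  cfg <- synth_config(n_chatters = 10)
  d <- withr::with_seed(1, rechat:::sample_delay(20000, cfg$recontact_delay))
  expect_gt(mean(d <= 7), 0.5)
  expect_true(all(d <= 188))
  expect_true(all(d > 0.25))  # always beyond the 6-hour session gap
})

test_that("message streams round-trip through JSONL and CSV", {
  corp <- generate_corpus(synth_config(n_chatters = 8, seed = 2))
  for (ext in c("jsonl", "csv")) {
    f <- file.path(tempdir(), paste0("msg.", ext))
    write_messages(corp$messages, f)
    back <- read_messages(f)
    expect_equal(back$chat_id, corp$messages$chat_id)
    expect_equal(back$text, corp$messages$text)
    expect_equal(as.numeric(back$sent_at),
                 floor(as.numeric(corp$messages$sent_at)))
  }
})

test_that("optional non-qualifying contacts appear at the configured share", {
  cfg <- synth_config(n_chatters = 300, seed = 11, emit_nonqualifying = TRUE)
  corp <- generate_corpus(cfg)
  rec <- build_episodes(corp$messages)
  excluded <- attr(rec, "n_excluded")
  expect_equal(excluded / nrow(corp$truth), 0.31, tolerance = 0.05)
  expect_true(all(rec$chat_id %in% corp$truth$chat_id[corp$truth$qualifies]))
})
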