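## Exact calibration of the generator: negative-binomial size/mean under the
## qualification truncation, and the logistic intercept behind the 43.1%
## recontact prevalence.

# size parameter of a negative binomial with given mean and sd (requires
# over-dispersion, validated in synth_config).
nb_size <- function(mean, sd) mean^2 / (sd^2 - mean)

# Exact moments of (chatter, counselor) message counts conditional on the
# qualification event {counselor >= min_counselor, total >= min_total},
# computed by summation over a truncated support grid.
truncated_count_moments <- function(mu_c, mu_k, size_c, size_k,
                                    min_counselor = 3L, min_total = 10L,
                                    cmax = 600L, kmax = 400L) {
  cs <- 0:cmax
  ks <- 0:kmax
  pc <- dnbinom(cs, size = size_c, mu = mu_c)
  pk <- dnbinom(ks, size = size_k, mu = mu_k)
  W <- outer(pc, pk) * outer(cs, ks, function(C, K)
    K >= min_counselor & C + K >= min_total)
  Z <- sum(W)
  rw <- Matrix::rowSums(W)
  cw <- Matrix::colSums(W)
  mc <- sum(rw * cs) / Z
  mk <- sum(cw * ks) / Z
  tot <- outer(cs, ks, "+")
  mt <- sum(W * tot) / Z
  list(mean_chatter = mc, mean_counselor = mk,
       sd_chatter = sqrt(sum(rw * cs^2) / Z - mc^2),
       sd_counselor = sqrt(sum(cw * ks^2) / Z - mk^2),
       mean_total = mt, var_total = sum(W * tot^2) / Z - mt^2,
       accept_prob = Z)
}

#' Calibrate message-count distributions under the qualification filter
#'
#' Finds underlying negative-binomial means for the chatter and counselor
#' message-count laws such that, *after* truncation to qualifying
#' consultations (>= `min_counselor` counselor messages and >= `min_total`
#' total), the conditional means equal the configured targets. The size
#' (dispersion) parameters are fixed by the configured mean/sd; the solve is
#' deterministic (exact grid expectation + Nelder-Mead).
#'
#' @param config A [synth_config()].
#' @param min_counselor,min_total Qualification thresholds.
#' @return List with adjusted means `mu_chatter`, `mu_counselor`, sizes,
#'   the achieved truncated moments, and the word-count surplus law
#'   (`words_extra_mean`, `words_extra_size`) used by [generate_corpus()].
#' @export
calibrate_counts <- function(config, min_counselor = 3L, min_total = 10L) {
  size_c <- nb_size(config$chatter_msg_dist$mean, config$chatter_msg_dist$sd)
  size_k <- nb_size(config$counselor_msg_dist$mean, config$counselor_msg_dist$sd)
  target_c <- config$chatter_msg_dist$mean
  target_k <- config$counselor_msg_dist$mean
  obj <- function(p) {
    m <- truncated_count_moments(p[1], p[2], size_c, size_k,
                                 min_counselor, min_total)
    (m$mean_chatter - target_c)^2 + (m$mean_counselor - target_k)^2
  }
  opt <- optim(c(target_c, target_k), obj,
               control = list(reltol = 1e-12, maxit = 500))
  if (opt$value > 1e-6)
    stop("count calibration failed to converge", call. = FALSE)
  mom <- truncated_count_moments(opt$par[1], opt$par[2], size_c, size_k,
                                 min_counselor, min_total)
  # Total words = n_total + surplus; the surplus mean/variance are set so the
  # word-count total hits the configured mean/sd without any truncation.
  wd <- config$total_words_dist
  extra_mean <- wd$mean - mom$mean_total
  extra_var <- wd$sd^2 - mom$var_total
  if (extra_mean <= 0 || extra_var <= extra_mean)
    stop("total_words_dist is inconsistent with the message-count law",
         call. = FALSE)
  list(mu_chatter = opt$par[1], mu_counselor = opt$par[2],
       size_chatter = size_c, size_counselor = size_k,
       moments = mom,
       words_extra_mean = extra_mean,
       words_extra_size = extra_mean^2 / (extra_var - extra_mean))
}

# Latent driver distribution implied by a config: independent Bernoulli
# indicators and their log-odds effects. Gender enters through a single
# binary (female), carrying effect_log_odds["female"] when 1 and
# effect_log_odds["male"] when 0.
latent_spec <- function(config) {
  ad <- config$age_dist
  tp <- config$topic_priors
  p_young <- sum(ad$probs[ad$values <= 15])
  p_night <- sum(config$start_time_dist[(0:23) %in% config$night_hours])
  eff <- config$effect_log_odds
  list(
    probs = c(young = p_young, female = config$p_female,
              self_harm = tp$self_harm, suicide = tp$suicide,
              night = p_night, work = tp$work, redirection = tp$redirection),
    effects = c(young = unname(eff["young"]), female = unname(eff["female"]),
                self_harm = unname(eff["self_harm"]),
                suicide = unname(eff["suicide"]),
                night = unname(eff["night"]), work = unname(eff["work"]),
                redirection = unname(eff["redirection"])),
    male_effect = unname(eff["male"])
  )
}

#' Calibrate the logistic intercept for the target recontact prevalence
#'
#' Solves for the intercept `b0` of the latent logistic outcome model so
#' that the marginal recontact probability under the configured latent
#' distribution equals `target_prevalence`. The expectation is exact: the
#' seven binary drivers are enumerated (2^7 cells) with their product
#' probabilities, and `b0` is found by root-finding on \[-10, 10\].
#'
#' @param config A [synth_config()].
#' @return The intercept `b0` (log-odds scale).
#' @export
calibrate_intercept <- function(config) {
  ls <- latent_spec(config)
  k <- length(ls$probs)
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(grid) <- names(ls$probs)
  cellp <- apply(grid, 1L, function(z)
    prod(ifelse(z == 1, ls$probs, 1 - ls$probs)))
  lp <- drop(grid %*% ls$effects) + (1 - grid[, "female"]) * ls$male_effect
  f <- function(b0) sum(cellp * plogis(b0 + lp)) - config$target_prevalence
  if (f(-10) > 0 || f(10) < 0)
    stop("no intercept in [-10, 10] achieves the target prevalence",
         call. = FALSE)
  uniroot(f, c(-10, 10), tol = 1e-10)$root
}
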