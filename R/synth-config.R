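#' Default topic lexicons for the synthetic corpus
#'
#' Small, pairwise-disjoint sets of (German-style) word stems, one per topic
#' the generator can activate in a chat. The `background` lexicon supplies the
#' bulk of every message; `redirection` stems are emitted only by counselors;
#' `numbers` carries the chatter's age as a literal token.
#'
#' @return Named list of character vectors.
#' @export
default_lexicons <- function() {
  list(
    self_harm = c("verletz", "ritz", "schneid", "narb", "wund", "klinge",
                  "blut", "harm"),
    suicide = c("suizid", "selbstmord", "sterb", "tod", "abschied",
                "umbring"),
    work = c("arbeit", "job", "chef", "ausbild", "kolleg", "schicht",
             "bewerbung", "praktikum"),
    redirection = c("professionell", "therapeut", "beratungsstell", "arzt",
                    "rat", "internetseelsorg", "hotline", "weiterleit"),
    time_of_day = c("nacht", "schlaf", "morg", "abend", "spat", "mud",
                    "bett", "tagsub"),
    emotion_adjectives = c("allein", "schwach", "falsch", "traurig", "leer",
                           "verzweifelt", "wertlos", "uberfordert",
                           "hoffnungslos", "erschopft"),
    numbers = as.character(12:24),
    background = c("ich", "du", "und", "nicht", "mit", "wie", "dass", "aber",
                   "mir", "mich", "dir", "wenn", "auch", "mal", "noch",
                   "schon", "dann", "was", "fur", "ist", "hab", "bin",
                   "kann", "mocht", "gern", "gut", "dank", "hallo", "hey",
                   "viel", "immer", "heut", "woch", "mutter", "vater",
                   "eltern", "freund", "schul", "lehrer", "klass", "gefuhl",
                   "angst", "sorg", "problem", "red", "sprech", "erzahl",
                   "versteh", "hilf", "frag", "zeit", "tag", "mensch",
                   "situation", "gedank", "streit", "famili", "wohn",
                   "stadt", "haus")
  )
}

#' Configuration of the synthetic chat-corpus generator
#'
#' Describes the statistical structure of the corpus the generator emulates:
#' over-dispersed per-consultation message counts, total word counts, a
#' 43.1\% recontact prevalence driven by latent chatter traits through a
#' logistic model, a recontact-delay mixture with most mass in the first
#' week, and topic lexicons whose activation carries the planted signal.
#'
#' Message counts are drawn from negative binomials matched to the configured
#' mean/sd and truncated so that every synthetic chatter's first consultation
#' qualifies (>= 3 counselor messages, >= 10 total). Because truncation
#' shifts moments, the underlying negative-binomial means are re-calibrated
#' exactly (grid summation + optimization) so the *truncated* means equal the
#' configured targets; see [calibrate_counts()].
#'
#' @param n_chatters Number of synthetic chatters (positive integer).
#' @param seed Integer RNG seed; the corpus is a deterministic function of
#'   the full configuration including this seed.
#' @param target_prevalence Marginal probability of recontact within the
#'   outcome window (default 0.431).
#' @param chatter_msg_dist,counselor_msg_dist Lists `list(mean=, sd=)` for
#'   the per-consultation message-count laws (defaults 25.4/20.8 and
#'   17.7/12.1).
#' @param total_words_dist List `list(mean=, sd=, cap=)` for total words
#'   exchanged in the first consultation (defaults 456.4/283.9, cap 3340).
#' @param age_dist List `list(values=, probs=)`, a discrete age distribution
#'   over 12-24 centered near 17.
#' @param p_female Probability a chatter is female (default 0.7; the service
#'   population is predominantly female).
#' @param topic_lexicons Named list of pairwise-disjoint stem vectors; see
#'   [default_lexicons()].
#' @param topic_priors Named list of activation probabilities. `time_of_day`
#'   and `emotion_adjectives` are length-2 (conditional on night start and
#'   female sex respectively); `numbers` is the probability the chatter's age
#'   token is emitted.
#' @param effect_log_odds Named numeric vector of log-odds effects of the
#'   latent drivers on recontact (positive: young, female, self_harm,
#'   suicide, night; negative: male, work, redirection).
#' @param mirror_prob Probability that a chatter topic is mirrored into the
#'   counselor's messages (default 2/3).
#' @param recontact_delay List describing the delay mixture: probability
#'   `p_week` of a uniform delay in `[min_days, week_max]` days, otherwise an
#'   exponential tail (mean `tail_mean`) truncated to `(week_max, max_days]`.
#' @param start_time_dist Numeric vector of 24 non-negative weights over the
#'   clock hour of the first message.
#' @param calendar Character vector `c(start, end)` of dates between which
#'   first contacts are spread uniformly.
#' @param night_hours Integer clock hours counted as night.
#' @param emit_nonqualifying If `TRUE`, additionally emit contacts that never
#'   reach a qualifying consultation, at rate `nonqualifying_rate` of all
#'   contacts (emulating the study's 31\% exclusion share).
#' @param nonqualifying_rate Share of all emitted chatters whose first
#'   contact does not qualify (used only when `emit_nonqualifying`).
#'
#' @return An object of class `synth_config` (a validated list).
#' @seealso [generate_corpus()], [calibrate_intercept()]
#' @export
synth_config <- function(n_chatters,
                         seed = 1L,
                         target_prevalence = 0.431,
                         chatter_msg_dist = list(mean = 25.4, sd = 20.8),
                         counselor_msg_dist = list(mean = 17.7, sd = 12.1),
                         total_words_dist = list(mean = 456.4, sd = 283.9,
                                                 cap = 3340),
                         age_dist = NULL,
                         p_female = 0.7,
                         topic_lexicons = default_lexicons(),
                         topic_priors = list(self_harm = 0.25,
                                             suicide = 0.15,
                                             work = 0.25,
                                             redirection = 0.35,
                                             time_of_day = c(night = 0.85,
                                                             day = 0.10),
                                             emotion_adjectives = c(female = 0.55,
                                                                    male = 0.30),
                                             numbers = 0.7),
                         effect_log_odds = c(young = 1.2, female = 0.5,
                                             male = -0.5, self_harm = 1.2,
                                             suicide = 1.3, night = 0.8,
                                             work = -1.0, redirection = -0.9),
                         mirror_prob = 2 / 3,
                         recontact_delay = list(p_week = 0.55, min_days = 0.3,
                                                week_max = 7, tail_mean = 40,
                                                max_days = 188),
                         start_time_dist = NULL,
                         calendar = c("2021-10-01", "2022-12-31"),
                         night_hours = c(22, 23, 0:5),
                         emit_nonqualifying = FALSE,
                         nonqualifying_rate = 0.31) {
  if (!is.numeric(n_chatters) || length(n_chatters) != 1L || n_chatters < 1)
    stop("`n_chatters` must be a positive integer", call. = FALSE)
  if (is.null(age_dist)) {
    v <- 12:24
    p <- dnorm(v, mean = 17, sd = 3)
    age_dist <- list(values = v, probs = p / sum(p))
  }
  if (is.null(start_time_dist)) {
    # diurnal profile: afternoon/evening peak, modest night share (~15%)
    w <- c(1.5, 1.5, 0.6, 0.6, 0.6, 0.6, 2, 2, 3, 3, 3, 3,
           4, 4, 4, 4, 4, 4, 3, 3, 2, 2, 1.5, 1.5)
    start_time_dist <- w / sum(w)
  }
  cfg <- structure(list(
    n_chatters = as.integer(n_chatters), seed = as.integer(seed),
    target_prevalence = target_prevalence,
    chatter_msg_dist = chatter_msg_dist,
    counselor_msg_dist = counselor_msg_dist,
    total_words_dist = total_words_dist,
    age_dist = age_dist, p_female = p_female,
    topic_lexicons = topic_lexicons, topic_priors = topic_priors,
    effect_log_odds = effect_log_odds, mirror_prob = mirror_prob,
    recontact_delay = recontact_delay,
    start_time_dist = start_time_dist / sum(start_time_dist),
    calendar = calendar, night_hours = as.integer(night_hours),
    emit_nonqualifying = isTRUE(emit_nonqualifying),
    nonqualifying_rate = nonqualifying_rate
  ), class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  assert_prob(cfg$target_prevalence, "target_prevalence")
  assert_prob(cfg$p_female, "p_female")
  assert_prob(cfg$mirror_prob, "mirror_prob")
  assert_prob(cfg$nonqualifying_rate, "nonqualifying_rate")
  for (d in c("chatter_msg_dist", "counselor_msg_dist", "total_words_dist")) {
    m <- cfg[[d]]
    if (m$mean <= 0 || m$sd <= 0)
      stop(sprintf("`%s` must have positive mean and sd", d), call. = FALSE)
    if (m$sd^2 <= m$mean)
      stop(sprintf("`%s` must be over-dispersed (sd^2 > mean)", d),
           call. = FALSE)
  }
  lex <- cfg$topic_lexicons
  all_stems <- unlist(lex, use.names = FALSE)
  if (anyDuplicated(all_stems))
    stop("topic lexicons must be pairwise disjoint; duplicated stems: ",
         paste(unique(all_stems[duplicated(all_stems)]), collapse = ", "),
         call. = FALSE)
  need <- c("self_harm", "suicide", "work", "redirection", "time_of_day",
            "background", "emotion_adjectives", "numbers")
  miss <- setdiff(need, names(lex))
  if (length(miss))
    stop("missing topic lexicons: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rd <- cfg$recontact_delay
  assert_prob(rd$p_week, "recontact_delay$p_week")
  if (delay_week_mass(rd) < 0.5)
    stop("recontact_delay must place at least half its mass within 7 days",
         call. = FALSE)
  if (abs(sum(cfg$age_dist$probs) - 1) > 1e-8)
    stop("age_dist probabilities must sum to 1", call. = FALSE)
  cfg
}

# Probability mass of the delay mixture falling in [0, 7] days.
delay_week_mass <- function(rd) {
  if (rd$week_max <= 7) rd$p_week else
    rd$p_week * (7 - rd$min_days) / (rd$week_max - rd$min_days)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  chatters: %d  seed: %d  target prevalence: %.3f\n",
              x$n_chatters, x$seed, x$target_prevalence))
  cat(sprintf("  chatter msgs  mean %.1f sd %.1f | counselor msgs mean %.1f sd %.1f\n",
              x$chatter_msg_dist$mean, x$chatter_msg_dist$sd,
              x$counselor_msg_dist$mean, x$counselor_msg_dist$sd))
  cat(sprintf("  total words   mean %.1f sd %.1f cap %d\n",
              x$total_words_dist$mean, x$total_words_dist$sd,
              as.integer(x$total_words_dist$cap)))
  cat(sprintf("  topics: %s\n", paste(names(x$topic_lexicons), collapse = ", ")))
  invisible(x)
}
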