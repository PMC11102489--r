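#' Area under the ROC curve via the rank statistic
#'
#' Computes AUROC as the normalized Mann-Whitney statistic with midranks
#' for ties: the probability that a randomly chosen positive is scored
#' above a randomly chosen negative (ties counting one half).
#'
#' @param labels Logical/0-1 outcome vector.
#' @param scores Numeric scores (higher = more likely positive).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  y <- as.logical(labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Holdout classification report at a probability threshold
#'
#' Computes AUROC plus the thresholded confusion counts and derived
#' metrics: accuracy, balanced accuracy, precision, recall, sensitivity
#' (identical to recall for the positive class) and specificity. When only
#' one class is present, AUROC is `NA` with a warning and the remaining
#' metrics are still returned.
#'
#' @param labels Logical/0-1 outcome vector (positive = recontact).
#' @param probabilities Predicted class probabilities in \[0, 1\].
#' @param threshold Classification threshold (default 0.5).
#' @return Object of class `eval_report`.
#' @export
metrics_report <- function(labels, probabilities, threshold = 0.5) {
  assert_prob(probabilities, "probabilities")
  y <- as.logical(labels)
  pred <- probabilities >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  n <- length(y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- if (length(unique(y)) == 2L) auroc(y, probabilities) else {
    warning("AUROC undefined with a single class", call. = FALSE)
    NA_real_
  }
  structure(list(
    auroc = auc,
    accuracy = (tp + tn) / n,
    balanced_accuracy = mean(c(sens, spec)),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = sens, sensitivity = sens, specificity = spec,
    tp = tp, fp = fp, tn = tn, fn = fn,
    n = n, threshold = threshold
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  AUROC %.2f | accuracy %.2f | balanced accuracy %.2f\n",
              x$auroc, x$accuracy, x$balanced_accuracy))
  cat(sprintf("  precision %.2f | recall/sensitivity %.2f | specificity %.2f\n",
              x$precision, x$recall, x$specificity))
  cat(sprintf("  confusion: TP %d FP %d TN %d FN %d (threshold %.2f)\n",
              x$tp, x$fp, x$tn, x$fn, x$threshold))
  invisible(x)
}

#' Corrected 5x2cv paired t-test between two pipelines
#'
#' Five replications of twofold cross-validation: in replication `i` the
#' units are split into stratified halves, both pipelines are trained on
#' half A and their AUROC difference is scored on half B (`d_i1`), then the
#' halves are swapped (`d_i2`). With per-replication mean `dbar_i` and
#' variance `s_i^2 = (d_i1 - dbar_i)^2 + (d_i2 - dbar_i)^2`, the statistic
#'
#'   t = d_11 / sqrt(mean(s_i^2))
#'
#' is referred to a t distribution with 5 degrees of freedom, two-sided.
#'
#' @param pipeline_a,pipeline_b Pipeline specs: lists with `fit(ids, labels)`
#'   and `predict(model, ids)`, e.g. from [text_pipeline()] /
#'   [baseline_pipeline()].
#' @param labels Outcome vector named by unit (chat) id.
#' @param seed Seed controlling the five splits.
#' @return Object of class `paired_5x2cv`: `t`, `df` (= 5), two-sided `p`,
#'   and the per-replication difference records.
#' @export
paired_5x2cv_test <- function(pipeline_a, pipeline_b, labels, seed = 1L) {
  ids <- names(labels)
  if (is.null(ids)) stop("`labels` must be named by unit id", call. = FALSE)
  y <- as.numeric(labels)
  diffs <- matrix(NA_real_, 5L, 2L,
                  dimnames = list(paste0("rep", 1:5), c("half1", "half2")))
  score_diff <- function(train_ids, test_ids) {
    ma <- pipeline_a$fit(train_ids, labels)
    mb <- pipeline_b$fit(train_ids, labels)
    auroc(labels[test_ids], pipeline_a$predict(ma, test_ids)) -
      auroc(labels[test_ids], pipeline_b$predict(mb, test_ids))
  }
  for (i in 1:5) {
    half <- stratified_folds(y, 2L, child_seed(seed, i))
    A <- ids[half == 1L]
    B <- ids[half == 2L]
    diffs[i, 1L] <- score_diff(A, B)
    diffs[i, 2L] <- score_diff(B, A)
  }
  dbar <- rowMeans(diffs)
  s2 <- (diffs[, 1L] - dbar)^2 + (diffs[, 2L] - dbar)^2
  denom <- sqrt(mean(s2))
  t <- if (denom == 0) {
    if (diffs[1L, 1L] == 0) 0 else sign(diffs[1L, 1L]) * Inf
  } else diffs[1L, 1L] / denom
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df = 5)
  structure(list(t = t, df = 5L, p = p, differences = diffs, s2 = s2),
            class = "paired_5x2cv")
}

#' @export
print.paired_5x2cv <- function(x, ...) {
  cat(sprintf("<paired_5x2cv> t = %.3f (df = 5), two-sided p = %.4f\n",
              x$t, x$p))
  invisible(x)
}

#' Label-permutation significance test for a fixed set of predictions
#'
#' Permutes the labels `n_perm` times with a seeded generator, recomputes
#' AUROC against the fixed probabilities, and reports the add-one-smoothed
#' empirical p value `(1 + #\{permuted >= observed\}) / (1 + n_perm)`.
#'
#' @param labels Logical/0-1 outcome vector.
#' @param probabilities Fixed predicted scores.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed.
#' @return Object of class `permutation_result`: `observed`, `n_perm`,
#'   `permuted` (the null AUROC sample) and `p`.
#' @export
permutation_test <- function(labels, probabilities, n_perm = 1000L,
                             seed = 1L) {
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  y <- as.logical(labels)
  obs <- auroc(y, probabilities)
  n1 <- sum(y)
  n0 <- sum(!y)
  r <- rank(probabilities)  # ranks are invariant under label permutation
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pos <- sample.int(length(y), n1)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 0))
  structure(list(observed = obs, n_perm = as.integer(n_perm),
                 permuted = perm,
                 p = (1 + sum(perm >= obs)) / (1 + n_perm)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed AUROC %.3f, p = %.4f (%d perms)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}
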