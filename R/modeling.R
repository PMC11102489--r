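#' Gradient-booster hyperparameters
#'
#' Defaults are the best-performing values found for the text pipeline
#' (eta 0.05, gamma 1.5, max_depth 8, min_child_weight 20, subsample 0.6,
#' colsample_bytree 0.9).
#'
#' @param eta Learning rate.
#' @param gamma Minimum loss reduction to make a further split on a leaf.
#' @param max_depth Maximum tree depth.
#' @param min_child_weight Minimum sum of instance hessian in a child.
#' @param subsample Row subsample ratio per boosting round.
#' @param colsample_bytree Column subsample ratio per tree.
#' @return Object of class `booster_params`.
#' @export
booster_params <- function(eta = 0.05, gamma = 1.5, max_depth = 8L,
                           min_child_weight = 20, subsample = 0.6,
                           colsample_bytree = 0.9) {
  stopifnot(eta > 0, gamma >= 0, max_depth >= 1,
            subsample > 0, subsample <= 1,
            colsample_bytree > 0, colsample_bytree <= 1)
  structure(list(eta = eta, gamma = gamma, max_depth = as.integer(max_depth),
                 min_child_weight = min_child_weight, subsample = subsample,
                 colsample_bytree = colsample_bytree),
            class = "booster_params")
}

#' Combined vectorizer + booster pipeline parameters
#'
#' @param vectorizer A [vectorizer_params()].
#' @param booster A [booster_params()].
#' @param nrounds Number of boosting rounds (default 500, no early
#'   stopping).
#' @return Object of class `pipeline_params`.
#' @export
pipeline_params <- function(vectorizer = vectorizer_params(),
                            booster = booster_params(),
                            nrounds = 500L) {
  structure(list(vectorizer = vectorizer, booster = booster,
                 nrounds = as.integer(nrounds)),
            class = "pipeline_params")
}

#' The joint hyperparameter search space
#'
#' The eleven discrete grids tuned simultaneously: the four vectorizer
#' document-frequency bounds, the idf switch, and the six booster
#' parameters.
#'
#' @return Named list of grids (each a vector of candidate values).
#' @export
table2_space <- function() {
  list(
    max_df_chatter = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0),
    min_df_chatter = c(1L, 2L, 5L, 10L, 25L, 50L, 75L, 100L, 150L, 200L),
    max_df_couns = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0),
    min_df_couns = c(1L, 2L, 5L, 10L, 25L, 50L, 75L, 100L, 150L, 200L),
    colsample_bytree = c(0.2, 0.4, 0.6, 0.7, 0.8, 0.9, 1.0),
    eta = c(0.005, 0.01, 0.05, 0.1, 0.2),
    gamma = c(0, 0.25, 0.5, 1, 1.5, 2, 5, 10),
    max_depth = c(2L, 4L, 6L, 8L, 10L, 12L, 14L, 16L),
    min_child_weight = c(1, 5, 10, 20),
    subsample = c(0.2, 0.4, 0.6, 0.7, 0.8, 0.9, 1.0),
    use_idf = c(TRUE, FALSE)
  )
}

# Build pipeline_params from one named point of the search space.
params_from_point <- function(point, nrounds = 500L) {
  pipeline_params(
    vectorizer = vectorizer_params(
      max_df_chatter = point$max_df_chatter,
      min_df_chatter = point$min_df_chatter,
      max_df_couns = point$max_df_couns,
      min_df_couns = point$min_df_couns,
      use_idf = point$use_idf),
    booster = booster_params(
      eta = point$eta, gamma = point$gamma, max_depth = point$max_depth,
      min_child_weight = point$min_child_weight,
      subsample = point$subsample,
      colsample_bytree = point$colsample_bytree),
    nrounds = nrounds)
}

# Train an xgboost booster with the logistic objective (single-threaded so
# results are reproducible under the seeded R RNG).
fit_booster <- function(X, y, booster, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
  with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eval_metric = "auc",
                  eta = booster$eta, gamma = booster$gamma,
                  max_depth = booster$max_depth,
                  min_child_weight = booster$min_child_weight,
                  subsample = booster$subsample,
                  colsample_bytree = booster$colsample_bytree,
                  nthread = 1L, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0))
}

#' Repeated cross-validated AUROC of one pipeline configuration
#'
#' For each repeat a fresh seeded stratified fold assignment is drawn
#' (repeat `r` uses seed `seed + r`); within each fold the vectorizer is
#' fitted on the training portion only, the booster is trained, and AUROC
#' is scored on the held-out portion.
#'
#' @param docs Anonymized training corpus (both channels).
#' @param labels Logical/0-1 outcome vector named by `chat_id`.
#' @param params A [pipeline_params()].
#' @param n_folds,n_repeats Cross-validation layout (defaults 5 x 5).
#' @param seed Base seed.
#' @return Object of class `cv_report`: matrix of `n_repeats * n_folds`
#'   scores, their mean and sd, and the evaluated parameters.
#' @export
cv_evaluate <- function(docs, labels, params = pipeline_params(),
                        n_folds = 5L, n_repeats = 5L, seed = 1L) {
  chats <- unique(docs$chat_id)
  y <- as.numeric(labels[chats])
  if (length(unique(y)) < 2L)
    stop("cv_evaluate requires both outcome classes", call. = FALSE)
  scores <- matrix(NA_real_, n_repeats, n_folds,
                   dimnames = list(paste0("rep", seq_len(n_repeats)),
                                   paste0("fold", seq_len(n_folds))))
  for (r in seq_len(n_repeats)) {
    fold <- valid_folds(y, n_folds, seed + r)
    for (f in seq_len(n_folds)) {
      tr <- chats[fold != f]
      te <- chats[fold == f]
      fit <- fit_text_fold(docs, labels, tr, params,
                           child_seed(seed, r * 100L + f))
      scores[r, f] <- auroc(labels[te], fit$predict(te))
    }
  }
  structure(list(scores = scores, mean = mean(scores), sd = sd(scores),
                 params = params),
            class = "cv_report")
}

# Stratified folds, resampled (up to 10 attempts) if any fold is
# single-class.
valid_folds <- function(y, k, seed) {
  for (a in 0:9) {
    fold <- stratified_folds(y, k, child_seed(seed, a))
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold == f])) == 2L, TRUE))
    if (ok) return(fold)
  }
  stop("could not build folds with both classes present", call. = FALSE)
}

# Fit vectorizer + booster on the training chats; returns a closure
# predicting probabilities for any chat subset.
fit_text_fold <- function(docs, labels, train_chats, params, seed) {
  dtr <- docs[docs$chat_id %in% train_chats, , drop = FALSE]
  vect <- fit_vectorizer(dtr, params$vectorizer)
  Xtr <- transform_docs(vect, dtr)[train_chats, , drop = FALSE]
  bst <- fit_booster(Xtr, labels[train_chats], params$booster,
                     params$nrounds, seed)
  list(vect = vect, booster = bst,
       predict = function(chat_ids) {
         dte <- docs[docs$chat_id %in% chat_ids, , drop = FALSE]
         X <- transform_docs(vect, dte)[chat_ids, , drop = FALSE]
         predict(bst, xgboost::xgb.DMatrix(X))
       })
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d scores, AUROC %.3f (sd %.3f)\n",
              length(x$scores), x$mean, x$sd))
  invisible(x)
}

#' Bayesian hyperparameter search over the discrete grids
#'
#' Sequential model-based optimization maximizing the cross-validated mean
#' AUROC from [cv_evaluate()]. Configurations are encoded as grid indices; a
#' random-forest surrogate is refitted after every evaluation and the next
#' configuration is chosen by expected improvement over a random candidate
#' pool. Deterministic given the seed.
#'
#' @inheritParams cv_evaluate
#' @param space Named list of grids, see [table2_space()].
#' @param n_iter Total number of configurations evaluated (default 250).
#' @param n_init Random initial design size before the surrogate starts.
#' @param nrounds Boosting rounds used for every evaluated configuration.
#' @param n_folds,n_repeats CV layout used to score each configuration.
#' @return List with `best_params` ([pipeline_params()]), `best_score`, and
#'   `trace` (one row per evaluated configuration with its score).
#' @export
bayes_search <- function(docs, labels, space = table2_space(),
                         n_iter = 250L, n_init = 10L, nrounds = 500L,
                         n_folds = 5L, n_repeats = 5L, seed = 1L) {
  if (n_iter < 1L) stop("`n_iter` must be >= 1", call. = FALSE)
  if (!length(space)) stop("empty search space", call. = FALSE)
  sizes <- lengths(space)
  n_conf <- prod(sizes)
  n_iter <- min(n_iter, n_conf)
  n_init <- min(max(2L, n_init), n_iter)

  decode <- function(idx) {
    point <- Map(function(grid, i) grid[i], space, as.list(idx))
    params_from_point(point, nrounds)
  }
  evaluated <- matrix(NA_integer_, 0L, length(space))
  scores <- numeric(0)
  seen <- character(0)

  sample_new <- function(n, rng_seed) {
    with_seed(rng_seed, {
      out <- matrix(NA_integer_, 0L, length(space))
      out_keys <- character(0)
      for (tries in 1:50) {
        cand <- vapply(sizes, function(s) sample.int(s, n, TRUE),
                       integer(n))
        if (n == 1L) cand <- matrix(cand, nrow = 1L)
        key <- apply(cand, 1L, paste, collapse = ",")
        fresh <- !(key %in% c(seen, out_keys)) & !duplicated(key)
        out <- rbind(out, cand[fresh, , drop = FALSE])
        out_keys <- c(out_keys, key[fresh])
        if (nrow(out) >= n) break
      }
      out[seq_len(min(n, nrow(out))), , drop = FALSE]
    })
  }

  eval_point <- function(idx, k) {
    p <- decode(idx)
    rep <- cv_evaluate(docs, labels, p, n_folds, n_repeats,
                       seed = child_seed(seed, 7L))
    evaluated <<- rbind(evaluated, idx)
    scores <<- c(scores, rep$mean)
    seen <<- c(seen, paste(idx, collapse = ","))
    rep$mean
  }

  init <- sample_new(n_init, child_seed(seed, 1L))
  for (i in seq_len(nrow(init))) eval_point(init[i, ], i)

  while (length(scores) < n_iter) {
    k <- length(scores)
    cand <- sample_new(min(1000L, n_conf), child_seed(seed, 100L + k))
    if (nrow(cand) == 0L) break
    nxt <- with_seed(child_seed(seed, 200L + k), {
      X <- as.data.frame(evaluated)
      # few distinct scores early in the search trip a regression warning
      rf <- suppressWarnings(
        randomForest::randomForest(X, scores, ntree = 200L))
      pr <- predict(rf, as.data.frame(cand), predict.all = TRUE)
      mu <- pr$aggregate
      sdv <- apply(pr$individual, 1L, sd)
      best <- max(scores)
      z <- ifelse(sdv > 0, (mu - best) / sdv, 0)
      ei <- ifelse(sdv > 0,
                   (mu - best) * stats::pnorm(z) + sdv * stats::dnorm(z),
                   pmax(mu - best, 0))
      cand[which.max(ei), ]
    })
    eval_point(nxt, k + 1L)
  }

  best <- which.max(scores)
  trace <- as.data.frame(evaluated)
  names(trace) <- names(space)
  for (j in seq_along(space)) trace[[j]] <- space[[j]][trace[[j]]]
  trace$score <- scores
  list(best_params = decode(evaluated[best, ]), best_score = scores[best],
       trace = trace)
}

#' Fit the final text pipeline on the whole training set
#'
#' Fits the vectorizer on all training documents and trains the booster
#' with the logistic objective. The returned model predicts probabilities
#' (or margins) for new document sets and can be saved and reloaded with
#' identical predictions.
#'
#' @inheritParams cv_evaluate
#' @param params Pipeline hyperparameters (default: the tuned values).
#' @return Object of class `rechat_model`.
#' @export
fit_final <- function(docs, labels, params = pipeline_params(), seed = 1L) {
  chats <- unique(docs$chat_id)
  vect <- fit_vectorizer(docs, params$vectorizer)
  X <- transform_docs(vect, docs)[chats, , drop = FALSE]
  bst <- fit_booster(X, labels[chats], params$booster, params$nrounds, seed)
  structure(list(vectorizer = vect, booster = bst, params = params,
                 feature_names = colnames(X)),
            class = "rechat_model")
}

#' Predict recontact probabilities for new documents
#'
#' @param object A fitted [fit_final()] model.
#' @param docs Anonymized corpus of the chats to score.
#' @param type `"prob"` for probabilities, `"margin"` for raw log-odds.
#' @param ... Unused.
#' @return Named numeric vector (one score per chat).
#' @export
predict.rechat_model <- function(object, docs, type = c("prob", "margin"),
                                 ...) {
  type <- match.arg(type)
  chats <- unique(docs$chat_id)
  X <- transform_docs(object$vectorizer, docs)[chats, , drop = FALSE]
  d <- xgboost::xgb.DMatrix(X)
  p <- if (type == "margin") predict(object$booster, d, outputmargin = TRUE)
  else predict(object$booster, d)
  setNames(p, chats)
}

#' Save / load a fitted model bundle
#'
#' The bundle directory holds the vectorizer JSON, the serialized booster,
#' and the pipeline parameters as YAML; reloading reproduces predictions
#' exactly.
#'
#' @param model A `rechat_model`.
#' @param dir Bundle directory (created if missing).
#' @return `save_model()` returns `dir` invisibly; `load_model()` the
#'   restored model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vectorizer(model$vectorizer, file.path(dir, "vectorizer.json"))
  xgboost::xgb.save(model$booster, file.path(dir, "booster.ubj"))
  yaml::write_yaml(list(
    booster = unclass(model$params$booster),
    nrounds = model$params$nrounds,
    feature_names = model$feature_names
  ), file.path(dir, "params.yaml"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  vect <- read_vectorizer(file.path(dir, "vectorizer.json"))
  meta <- yaml::read_yaml(file.path(dir, "params.yaml"))
  structure(list(
    vectorizer = vect,
    booster = xgboost::xgb.load(file.path(dir, "booster.ubj")),
    params = pipeline_params(vect$params,
                             do.call(booster_params, meta$booster),
                             meta$nrounds),
    feature_names = unlist(meta$feature_names)
  ), class = "rechat_model")
}

#' Pipeline factories for paired classifier comparisons
#'
#' Build the abstract fit/predict pairs consumed by
#' [paired_5x2cv_test()]: `text_pipeline()` trains the two-channel TF-IDF +
#' booster pipeline on a document corpus; `baseline_pipeline()` trains a
#' booster on the word-count + time-of-day metadata features.
#'
#' @param docs Anonymized corpus (text pipeline).
#' @param records Episode table (baseline pipeline).
#' @param params Pipeline parameters (text) / booster parameters plus
#'   `nrounds` (baseline).
#' @param nrounds Boosting rounds for the baseline pipeline.
#' @param seed Seed used for booster training.
#' @return List with functions `fit(ids)` returning a model and
#'   `predict(model, ids)` returning probabilities; `ids` are chat ids.
#' @export
text_pipeline <- function(docs, params = pipeline_params(), seed = 1L) {
  list(
    fit = function(ids, labels) {
      fit_text_fold(docs, labels, ids, params, seed)
    },
    predict = function(model, ids) model$predict(ids)
  )
}

#' @rdname text_pipeline
#' @export
baseline_pipeline <- function(records, params = booster_params(),
                              nrounds = 200L, seed = 1L) {
  M <- baseline_matrix(records)
  list(
    fit = function(ids, labels) {
      fit_booster(M[ids, , drop = FALSE], labels[ids], params, nrounds,
                  seed)
    },
    predict = function(model, ids) {
      setNames(predict(model, xgboost::xgb.DMatrix(M[ids, , drop = FALSE])),
               ids)
    }
  )
}
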