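#' Per-feature SHAP attributions for a fitted pipeline
#'
#' Exact tree-path (TreeSHAP) attributions for every sample and feature,
#' computed by the booster's own tree explainer on the margin (log-odds)
#' scale. Local accuracy holds per sample: the base value plus the row sum
#' of attributions reproduces the model's margin output.
#'
#' @param model A fitted [fit_final()] model.
#' @param docs Anonymized corpus of the chats to attribute.
#' @return Object of class `shap_report`: `base_value`, `shap` (sample x
#'   feature matrix), `mean_abs` (named per-feature mean absolute
#'   attribution, sorted decreasing), `feature_names`, `margin` (the model
#'   outputs), and per-channel included-stem counts.
#' @export
shap_attribution <- function(model, docs) {
  if (!inherits(model, "rechat_model"))
    stop("`model` must be a fitted rechat_model (tree ensemble)",
         call. = FALSE)
  chats <- unique(docs$chat_id)
  X <- transform_docs(model$vectorizer, docs)[chats, , drop = FALSE]
  d <- xgboost::xgb.DMatrix(X)
  contrib <- predict(model$booster, d, predcontrib = TRUE)
  base <- contrib[1L, ncol(contrib)]
  shap <- contrib[, -ncol(contrib), drop = FALSE]
  colnames(shap) <- colnames(X)
  rownames(shap) <- chats
  mean_abs <- sort(colMeans(abs(shap)), decreasing = TRUE)
  structure(list(
    base_value = base, shap = shap, mean_abs = mean_abs,
    feature_names = colnames(X),
    margin = predict(model$booster, d, outputmargin = TRUE),
    n_chatter_features = sum(startsWith(colnames(X), "ch_")),
    n_couns_features = sum(startsWith(colnames(X), "co_"))
  ), class = "shap_report")
}

#' @export
print.shap_report <- function(x, ...) {
  cat(sprintf("<shap_report> %d samples x %d features (%d chatter / %d counselor)\n",
              nrow(x$shap), ncol(x$shap), x$n_chatter_features,
              x$n_couns_features))
  cat("  top stems by mean |SHAP|:\n")
  top <- head(x$mean_abs, 10L)
  for (i in seq_along(top))
    cat(sprintf("    %-20s %.4f\n", names(top)[i], top[i]))
  invisible(x)
}

#' Cross-channel co-occurrence table for a target stem
#'
#' Restricts the corpus to chats whose `target_channel` document contains
#' `target_stem` and counts, for every stem of the opposite channel, the
#' number of those chats containing it, along with the share of target
#' chats covered. Also reports the cross-channel share of the target stem
#' itself (the mirroring share).
#'
#' @param docs Anonymized corpus (`chat_id`, `channel`, `stems`).
#' @param target_stem Stem to condition on.
#' @param target_channel `"chatter"` or `"counselor"`.
#' @param top_k Number of co-occurring stems to keep (default 20).
#' @return Data frame (`stem`, `n_chats`, `share`) sorted by count, with
#'   attributes `n_target_chats` and `cross_channel_share` (share of target
#'   chats whose *other* channel also contains the target stem).
#' @export
cooccurrence <- function(docs, target_stem, target_channel = "counselor",
                         top_k = 20L) {
  other_channel <- setdiff(c("chatter", "counselor"), target_channel)
  tgt <- docs[docs$channel == target_channel, , drop = FALSE]
  hit <- vapply(tgt$stems, function(s) target_stem %in% s, TRUE)
  target_chats <- tgt$chat_id[hit]
  if (!length(target_chats)) {
    out <- data.frame(stem = character(), n_chats = integer(),
                      share = numeric())
    attr(out, "n_target_chats") <- 0L
    attr(out, "cross_channel_share") <- NA_real_
    return(out)
  }
  oth <- docs[docs$channel == other_channel &
                docs$chat_id %in% target_chats, , drop = FALSE]
  u <- lapply(oth$stems, unique)
  tab <- sort(table(unlist(u, use.names = FALSE)), decreasing = TRUE)
  cross <- unname(tab[target_stem])
  out <- data.frame(stem = names(tab), n_chats = as.integer(tab),
                    share = as.numeric(tab) / length(target_chats),
                    stringsAsFactors = FALSE)
  out <- head(out, top_k)
  rownames(out) <- NULL
  attr(out, "n_target_chats") <- length(target_chats)
  attr(out, "cross_channel_share") <-
    if (is.na(cross) || !length(cross)) 0 else cross / length(target_chats)
  out
}

#' Read word embeddings in word2vec text format
#'
#' Parses the plain-text word2vec format: an optional `n dim` header line
#' followed by one `word v1 ... vd` line per word.
#'
#' @param path File path.
#' @return Numeric matrix with one row per word (rownames = words).
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && !grepl("[^0-9 ]", lines[1L])) lines <- lines[-1L]
  parts <- strsplit(lines, " +")
  words <- vapply(parts, `[[`, "", 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                   numeric(length(parts[[1L]]) - 1L)))
  rownames(vecs) <- words
  vecs
}

#' Train count-based word embeddings on a pre-shuffle corpus
#'
#' Builds distributional word vectors from windowed co-occurrence counts
#' via positive pointwise mutual information (PPMI) followed by a truncated
#' SVD -- a count-based factorization closely related to skip-gram with
#' negative sampling. Intended as the built-in embedding provider when no
#' pretrained word2vec file is supplied; train it on message texts *before*
#' shuffling, since shuffling destroys word order.
#'
#' @param texts Character vector of message texts (word order intact).
#' @param dim Embedding dimension (default 50).
#' @param window Symmetric context window in tokens (default 5).
#' @param min_count Minimum corpus frequency for a word to be embedded.
#' @return Numeric matrix, one row per embedded word.
#' @export
train_embeddings <- function(texts, dim = 50L, window = 5L,
                             min_count = 2L) {
  toks <- strsplit(tolower(texts), "[[:space:]]+")
  words <- unlist(toks, use.names = FALSE)
  words <- words[nzchar(words)]
  freq <- table(words)
  vocab <- sort(names(freq)[freq >= min_count])
  if (length(vocab) < 2L) stop("vocabulary too small to embed", call. = FALSE)
  wid <- lapply(toks, function(w) match(w[nzchar(w)], vocab))
  ii <- jj <- integer(0)
  for (off in seq_len(window)) {
    a <- unlist(lapply(wid, function(x)
      if (length(x) > off) x[seq_len(length(x) - off)] else integer(0)))
    b <- unlist(lapply(wid, function(x)
      if (length(x) > off) x[-seq_len(off)] else integer(0)))
    ok <- !is.na(a) & !is.na(b)
    ii <- c(ii, a[ok], b[ok])
    jj <- c(jj, b[ok], a[ok])
  }
  C <- sparseMatrix(i = ii, j = jj, x = 1,
                    dims = c(length(vocab), length(vocab)))
  total <- sum(C)
  rs <- Matrix::rowSums(C)
  M <- as.matrix(C) * total / outer(rs, rs)
  M <- log(pmax(M, 1))  # positive PMI
  dim <- min(dim, ncol(M))
  sv <- svd(M, nu = dim, nv = 0)
  emb <- sv$u %*% diag(sqrt(sv$d[seq_len(dim)]), dim)
  rownames(emb) <- vocab
  emb
}

#' Cluster embedded stems and sum attributions per cluster
#'
#' Runs seeded k-means (Lloyd's algorithm with multiple random restarts)
#' on the embedding vectors of the stems for every candidate `k`, chooses
#' `k` by the maximal mean silhouette score (optionally subject to a
#' usability minimum), and sums each cluster's mean-absolute attributions.
#' Stems without an embedding vector are excluded and counted.
#'
#' @param stems Character vector of stems to cluster (channel prefixes
#'   `ch_`/`co_` are stripped before the embedding lookup).
#' @param importances Numeric vector of mean absolute attributions, aligned
#'   with `stems`.
#' @param embeddings Embedding matrix (rownames = words), e.g. from
#'   [train_embeddings()] or [read_word2vec()].
#' @param k_range Candidate cluster counts (default 5 to 40).
#' @param min_k Usability lower bound on the chosen `k` (default: none).
#' @param n_restarts Random restarts per `k` (default 10).
#' @param seed Seed.
#' @return Object of class `cluster_report`: `assignment` (named by stem),
#'   `k`, `silhouette` (data frame k/score), per-cluster `importance` and
#'   `size`, and `n_embedded`.
#' @export
embed_cluster <- function(stems, importances, embeddings, k_range = 5:40,
                          min_k = NULL, n_restarts = 10L, seed = 1L) {
  bare <- sub("^(ch|co)_", "", stems)
  found <- bare %in% rownames(embeddings)
  if (!is.null(min_k)) k_range <- k_range[k_range >= min_k]
  k_range <- k_range[k_range < sum(found)]
  if (!length(k_range) || sum(found) < 3L)
    stop("fewer embeddable stems than the smallest usable k", call. = FALSE)
  V <- embeddings[bare[found], , drop = FALSE]
  rownames(V) <- stems[found]
  D <- as.matrix(stats::dist(V))
  sil <- vapply(seq_along(k_range), function(i) {
    km <- kmeans_restarts(V, k_range[i], n_restarts,
                          child_seed(seed, k_range[i]))
    mean(cluster::silhouette(km$cluster, dmatrix = D)[, "sil_width"])
  }, 0)
  k <- k_range[which.max(sil)]
  km <- kmeans_restarts(V, k, n_restarts, child_seed(seed, k))
  imp <- importances[found]
  by_cl <- tapply(imp, km$cluster, sum)
  structure(list(
    assignment = setNames(km$cluster, stems[found]),
    k = k,
    silhouette = data.frame(k = k_range, score = sil),
    importance = as.numeric(by_cl)[order(-as.numeric(by_cl))],
    cluster_order = as.integer(names(by_cl))[order(-as.numeric(by_cl))],
    size = as.integer(table(km$cluster)),
    n_embedded = sum(found),
    n_missing = sum(!found)
  ), class = "cluster_report")
}

# Seeded Lloyd k-means with explicit random restarts; keeps the restart
# with the lowest total within-cluster sum of squares.
kmeans_restarts <- function(V, k, n_restarts, seed) {
  with_seed(seed, {
    best <- NULL
    for (j in seq_len(n_restarts)) {
      centers <- V[sample.int(nrow(V), k), , drop = FALSE]
      km <- suppressWarnings(
        kmeans(V, centers = centers, iter.max = 100L, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> k = %d over %d embedded stems (%d without vectors)\n",
              x$k, x$n_embedded, x$n_missing))
  cat(sprintf("  top cluster importances: %s\n",
              paste(sprintf("%.3f", head(x$importance, 5L)),
                    collapse = ", ")))
  invisible(x)
}

#' Write explainability reports as CSV
#'
#' @param shap A `shap_report`.
#' @param path Output CSV path (feature, channel, mean |SHAP|).
#' @export
write_shap_csv <- function(shap, path) {
  df <- data.frame(
    feature = sub("^(ch|co)_", "", names(shap$mean_abs)),
    channel = ifelse(startsWith(names(shap$mean_abs), "ch_"),
                     "chatter", "counselor"),
    mean_abs_shap = as.numeric(shap$mean_abs))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
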