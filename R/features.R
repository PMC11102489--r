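#' Vectorizer hyperparameters for the two-channel TF-IDF features
#'
#' `min_df` bounds are absolute chat counts; `max_df` bounds are proportions
#' of the channel's training documents. Defaults are the best-performing
#' values of the tuned pipeline (chatter: max_df 0.8 / min_df 150;
#' counselor: max_df 0.3 / min_df 75; no idf reweighting).
#'
#' @param max_df_chatter,max_df_couns Maximum document proportion for a term
#'   to be kept, per channel.
#' @param min_df_chatter,min_df_couns Minimum absolute number of chats a
#'   term must appear in, per channel.
#' @param use_idf Reweight term frequencies by smoothed inverse document
#'   frequency (`log((1 + N) / (1 + df)) + 1`)?
#' @return Object of class `vectorizer_params`.
#' @export
vectorizer_params <- function(max_df_chatter = 0.8, min_df_chatter = 150L,
                              max_df_couns = 0.3, min_df_couns = 75L,
                              use_idf = FALSE) {
  stopifnot(max_df_chatter > 0, max_df_chatter <= 1,
            max_df_couns > 0, max_df_couns <= 1,
            min_df_chatter >= 1, min_df_couns >= 1)
  structure(list(max_df_chatter = max_df_chatter,
                 min_df_chatter = as.integer(min_df_chatter),
                 max_df_couns = max_df_couns,
                 min_df_couns = as.integer(min_df_couns),
                 use_idf = isTRUE(use_idf)),
            class = "vectorizer_params")
}

#' Fit the two-channel TF-IDF vectorizer on training documents
#'
#' Per channel, the vocabulary consists of stems whose chat-document
#' frequency is at least the channel's `min_df` (absolute count) and at most
#' `max_df` (proportion of that channel's training documents). When
#' `use_idf`, smoothed idf weights are computed; otherwise all weights are 1.
#' The fitted vocabulary is frozen: transforming held-out documents ignores
#' out-of-vocabulary stems.
#'
#' @param docs Anonymized corpus (data frame `chat_id`, `channel`, `stems`)
#'   restricted to the training chats.
#' @param params A [vectorizer_params()].
#' @return Object of class `rechat_vectorizer` holding per-channel
#'   vocabularies and idf weights.
#' @export
fit_vectorizer <- function(docs, params = vectorizer_params()) {
  fit_channel <- function(channel, min_df, max_df) {
    d <- docs[docs$channel == channel, , drop = FALSE]
    n <- nrow(d)
    stem <- unlist(d$stems, use.names = FALSE)
    doc <- rep.int(seq_len(n), lengths(d$stems))
    first <- !duplicated(paste0(doc, "\r", stem))
    df <- table(stem[first])
    vocab <- sort(names(df)[df >= min_df & df <= max_df * n])
    if (!length(vocab))
      stop(sprintf("empty %s vocabulary after df filtering", channel),
           call. = FALSE)
    idf <- if (params$use_idf)
      log((1 + n) / (1 + as.numeric(df[vocab]))) + 1
    else rep(1, length(vocab))
    list(vocab = vocab, idf = setNames(idf, vocab), n_docs = n)
  }
  structure(list(
    chatter = fit_channel("chatter", params$min_df_chatter,
                          params$max_df_chatter),
    counselor = fit_channel("counselor", params$min_df_couns,
                            params$max_df_couns),
    params = params
  ), class = "rechat_vectorizer")
}

#' @export
print.rechat_vectorizer <- function(x, ...) {
  cat(sprintf("<rechat_vectorizer> %d chatter + %d counselor stems (idf: %s)\n",
              length(x$chatter$vocab), length(x$counselor$vocab),
              if (x$params$use_idf) "smoothed" else "none"))
  invisible(x)
}

#' Transform documents into the concatenated two-channel feature matrix
#'
#' Per channel: raw term counts per document, optionally multiplied by the
#' fitted idf weights, then Euclidean-normalized per channel vector. The two
#' channel blocks are concatenated per chatter, with `ch_`/`co_` column-name
#' prefixes. Out-of-vocabulary stems are ignored; a document with no
#' in-vocabulary stem yields an all-zero block.
#'
#' @param vect A fitted [fit_vectorizer()] object.
#' @param docs Anonymized corpus (both channels) for the chats to transform.
#' @return Sparse `dgCMatrix` with one row per chat (rownames = chat ids).
#' @export
transform_docs <- function(vect, docs) {
  chats <- unique(docs$chat_id)
  block <- function(channel, prefix) {
    st <- vect[[channel]]
    d <- docs[docs$channel == channel, , drop = FALSE]
    row <- match(d$chat_id, chats)
    stem <- unlist(d$stems, use.names = FALSE)
    ri <- rep.int(row, lengths(d$stems))
    ci <- match(stem, st$vocab)
    ok <- !is.na(ci)
    X <- sparseMatrix(i = ri[ok], j = ci[ok], x = 1,
                      dims = c(length(chats), length(st$vocab)))
    X <- X %*% Diagonal(x = unname(st$idf))
    nrm <- sqrt(Matrix::rowSums(X^2))
    nrm[nrm == 0] <- 1
    X <- Diagonal(x = 1 / nrm) %*% X
    colnames(X) <- paste0(prefix, st$vocab)
    X
  }
  out <- cbind(block("chatter", "ch_"), block("counselor", "co_"))
  rownames(out) <- chats
  methods::as(out, "CsparseMatrix")
}

#' Metadata baseline features: word counts and time of day
#'
#' The three-column baseline design: chatter word count, counselor word
#' count, and the clock hour (0-23) of the index consultation's first
#' message.
#'
#' @param records Episode table from [build_episodes()].
#' @return Numeric matrix with columns `wc_chatter`, `wc_counselor`,
#'   `start_hour` (rownames = chat ids).
#' @export
baseline_matrix <- function(records) {
  m <- cbind(wc_chatter = records$wc_chatter,
             wc_counselor = records$wc_counselor,
             start_hour = records$start_hour)
  rownames(m) <- records$chat_id
  m
}

#' Serialize / restore a fitted vectorizer as JSON
#'
#' @param vect Fitted vectorizer.
#' @param path JSON file path.
#' @return `write_vectorizer()` returns `path` invisibly;
#'   `read_vectorizer()` returns the restored `rechat_vectorizer`.
#' @export
write_vectorizer <- function(vect, path) {
  payload <- list(
    params = unclass(vect$params),
    chatter = list(vocab = vect$chatter$vocab,
                   idf = unname(vect$chatter$idf),
                   n_docs = vect$chatter$n_docs),
    counselor = list(vocab = vect$counselor$vocab,
                     idf = unname(vect$counselor$idf),
                     n_docs = vect$counselor$n_docs))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vectorizer
#' @export
read_vectorizer <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    chatter = list(vocab = p$chatter$vocab,
                   idf = setNames(p$chatter$idf, p$chatter$vocab),
                   n_docs = p$chatter$n_docs),
    counselor = list(vocab = p$counselor$vocab,
                     idf = setNames(p$counselor$idf, p$counselor$vocab),
                     n_docs = p$counselor$n_docs),
    params = do.call(vectorizer_params, p$params)
  ), class = "rechat_vectorizer")
}
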