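#' Anonymization configuration
#'
#' Settings for the privacy-preserving transformation: PII replacement
#' lists, the replacement tokens, the rare-word deletion threshold, the
#' shuffle seed and a pluggable stemmer.
#'
#' @param name_list,city_list Character vectors of names / city names to
#'   replace (matched case-insensitively as whole tokens); may be empty.
#' @param name_token,city_token Replacement tokens (must not collide with
#'   vocabulary words; the defaults are bracketed for that reason).
#' @param min_chats A stem must appear in at least this many distinct chats
#'   to survive rare-word deletion (default 5; stems in fewer than
#'   `min_chats` chats are removed).
#' @param shuffle_seed Seed for the within-speaker word shuffle.
#' @param stemmer Function mapping a character vector of tokens to stems;
#'   the default identity suits corpora whose tokens already are stems
#'   (e.g. the synthetic generator). Plug in a language-specific snowball
#'   stemmer for real text.
#' @return Object of class `anon_config`.
#' @export
anon_config <- function(name_list = character(), city_list = character(),
                        name_token = "[NAME]", city_token = "[CITY]",
                        min_chats = 5L, shuffle_seed = 1L,
                        stemmer = identity) {
  if (min_chats < 1L) stop("`min_chats` must be >= 1", call. = FALSE)
  if (name_token == city_token)
    stop("replacement tokens must be distinct", call. = FALSE)
  structure(list(name_list = tolower(name_list),
                 city_list = tolower(city_list),
                 name_token = name_token, city_token = city_token,
                 min_chats = as.integer(min_chats),
                 shuffle_seed = as.integer(shuffle_seed),
                 stemmer = stemmer),
            class = "anon_config")
}

#' Replace listed names and city names with privacy tokens
#'
#' Every whole-token, case-insensitive match of a listed name or city is
#' replaced by the configured token; all other tokens (including their
#' capitalization and adjacent punctuation) are untouched.
#'
#' @param text Character vector of raw message texts.
#' @param cfg An [anon_config()].
#' @return Character vector of the same length.
#' @export
replace_pii <- function(text, cfg) {
  if (!length(cfg$name_list) && !length(cfg$city_list)) return(text)
  vapply(strsplit(text, "(?<=[[:space:]])", perl = TRUE), function(toks) {
    core <- tolower(gsub("^[[:punct:]]+|[[:punct:][:space:]]+$", "", toks))
    toks[core %in% cfg$name_list] <- sub_core(toks[core %in% cfg$name_list],
                                              cfg$name_token)
    toks[core %in% cfg$city_list] <- sub_core(toks[core %in% cfg$city_list],
                                              cfg$city_token)
    paste(toks, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Swap the alphanumeric core of a token for `token`, keeping surrounding
# punctuation/whitespace.
sub_core <- function(toks, token) {
  gsub("[^[:punct:][:space:]]+([[:punct:]]*[^[:punct:][:space:]]+)*",
       token, toks)
}

#' Tokenize raw text for vectorization
#'
#' Lowercases, splits on whitespace, and strips leading/trailing
#' punctuation. Digits are kept as tokens, and the PII replacement tokens
#' pass through verbatim.
#'
#' @param text Character scalar or vector (elements are concatenated).
#' @param cfg An [anon_config()] (supplies the protected tokens).
#' @return Character vector of tokens.
#' @export
tokenize <- function(text, cfg = anon_config()) {
  toks <- unlist(strsplit(text, "[[:space:]]+"), use.names = FALSE)
  toks <- toks[nzchar(toks)]
  protected <- toks %in% c(cfg$name_token, cfg$city_token)
  toks[!protected] <- gsub("^[[:punct:]]+|[[:punct:]]+$", "",
                           tolower(toks[!protected]))
  toks[nzchar(toks)]
}

#' Map tokens through the configured stemmer
#'
#' The PII replacement tokens pass through unchanged; every other token is
#' mapped through `cfg$stemmer`.
#'
#' @param tokens Character vector of tokens.
#' @param cfg An [anon_config()].
#' @return Character vector of stems.
#' @export
stem_tokens <- function(tokens, cfg) {
  protected <- tokens %in% c(cfg$name_token, cfg$city_token)
  tokens[!protected] <- cfg$stemmer(tokens[!protected])
  tokens
}

#' Shuffle stems into random order within one speaker document
#'
#' Applies a seeded uniform permutation; the stem multiset is unchanged.
#'
#' @param stems Character vector of stems.
#' @param seed Integer seed.
#' @return Permuted character vector.
#' @export
shuffle_within_speaker <- function(stems, seed) {
  if (length(stems) < 2L) return(stems)
  with_seed(seed, sample(stems))
}

#' Delete stems present in fewer than `min_chats` distinct chats
#'
#' Chat-level presence is computed over the full corpus, counting both
#' channels of a chat as one chat. Stems appearing in exactly `min_chats`
#' chats are retained.
#'
#' @param docs Anonymized corpus: data frame with columns `chat_id`,
#'   `channel`, and list-column `stems`.
#' @param min_chats Deletion threshold (default 5).
#' @return `docs` with rare stems removed from every document; attribute
#'   `removed` holds the deleted stems.
#' @export
prune_rare <- function(docs, min_chats = 5L) {
  if (nrow(docs) == 0L) return(docs)
  chat <- rep.int(docs$chat_id, lengths(docs$stems))
  stem <- unlist(docs$stems, use.names = FALSE)
  first <- !duplicated(paste0(chat, "\r", stem))
  df <- table(stem[first])
  keep <- names(df)[df >= min_chats]
  docs$stems <- lapply(docs$stems, function(s) s[s %in% keep])
  attr(docs, "removed") <- setdiff(names(df), keep)
  docs
}

#' Run the full anonymization pipeline over speaker documents
#'
#' Applies, in the order used for the privacy export: PII token
#' replacement, tokenization, stemming, a seeded within-speaker shuffle,
#' and rare-word deletion (on the full corpus, before any train/test
#' split; set `prune = FALSE` to defer pruning).
#'
#' @param docs Data frame from [collect_speaker_docs()]: `chat_id`,
#'   `channel`, `text`.
#' @param cfg An [anon_config()].
#' @param prune Apply rare-word deletion (default `TRUE`).
#' @return Data frame `chat_id`, `channel`, with list-column `stems`.
#' @export
anonymize_corpus <- function(docs, cfg = anon_config(), prune = TRUE) {
  txt <- replace_pii(docs$text, cfg)
  stems <- lapply(seq_along(txt), function(i)
    shuffle_within_speaker(
      stem_tokens(tokenize(txt[i], cfg), cfg),
      child_seed(cfg$shuffle_seed, i)))
  out <- data.frame(chat_id = docs$chat_id, channel = docs$channel,
                    stringsAsFactors = FALSE)
  out$stems <- stems
  if (prune) out <- prune_rare(out, cfg$min_chats)
  out
}

#' Write anonymized documents as JSONL
#'
#' One object per speaker document with keys `chat_id`, `channel` and
#' `text` (space-joined shuffled stems).
#'
#' @param docs Anonymized corpus from [anonymize_corpus()].
#' @param path Output path.
#' @export
write_anonymized <- function(docs, path) {
  df <- data.frame(chat_id = docs$chat_id, channel = docs$channel,
                   text = vapply(docs$stems, paste, "", collapse = " "),
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}
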