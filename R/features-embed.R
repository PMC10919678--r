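# Chunked token-embedding features.
#
# Transformer encoders cap input length (typically 512 tokens) while operative
# notes run longer, so notes are split into contiguous chunks, each chunk is
# embedded, and per-token / per-chunk-summary vectors are pooled into one
# document vector. The pooling modes mirror the usual conventions:
#   A_W / M_W  - elementwise mean / max over ALL tokens of all chunks
#   A_CLS / M_CLS - mean / max over the chunk-summary ([CLS]-role) vectors
# and any ordered pair of distinct modes concatenates the two vectors.

#' Split a token sequence into contiguous chunks
#'
#' Greedy split: every chunk has at most `max_chunk` tokens, chunks
#' concatenate back to the input, and no chunk is empty.
#'
#' @param tokens Character vector of tokens.
#' @param max_chunk Maximum tokens per chunk (>= 1).
#' @return List of token vectors (empty list for empty input).
#' @export
chunk_tokens <- function(tokens, max_chunk) {
  if (!is_count(max_chunk)) stop_bad("max_chunk must be a positive integer")
  if (length(tokens) == 0) return(list())
  unname(split(tokens, ceiling(seq_along(tokens) / max_chunk)))
}

#' An embedding backend contract
#'
#' A backend is a list with fields `embed_chunk(tokens)` returning
#' `list(tokens = <T x dim matrix>, summary = <dim vector>)`, plus integers
#' `max_chunk` and `dim`. The summary vector plays the role of a [CLS]
#' whole-chunk representation. `hash_embedding_backend()` is the package's
#' default: each token maps to a fixed pseudo-random Gaussian vector derived
#' from a hash of the token string and the backend seed, and the chunk
#' summary is the mean token vector. It is deterministic across sessions,
#' needs no model download, and exercises every aggregation path; a
#' transformer encoder (e.g. a clinically pre-trained BERT) can be plugged in
#' behind the same contract.
#'
#' @param dim Embedding dimension.
#' @param max_chunk Maximum chunk length.
#' @param seed Integer; together with the token string determines the vector.
#' @return A backend list with `embed_chunk`, `max_chunk`, `dim`.
#' @export
hash_embedding_backend <- function(dim = 32, max_chunk = 512, seed = 0) {
  stopifnot(is_count(dim), is_count(max_chunk))
  cache <- new.env(parent = emptyenv())
  token_vec <- function(tok) {
    v <- cache[[tok]]
    if (is.null(v)) {
      h <- string_hash(tok)
      v <- with_seed(derive_seed(seed, h), stats::rnorm(dim))
      cache[[tok]] <- v
    }
    v
  }
  list(
    embed_chunk = function(tokens) {
      if (length(tokens) == 0) stop_bad("cannot embed an empty chunk")
      m <- t(vapply(tokens, token_vec, numeric(dim)))
      list(tokens = m, summary = colMeans(m))
    },
    max_chunk = as.integer(max_chunk),
    dim = as.integer(dim)
  )
}

# deterministic 31-ary polynomial string hash in [0, 2^31 - 2]
string_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

#' Pool chunk embeddings into one document vector
#'
#' @param chunk_embeddings List of `embed_chunk()` outputs (>= 1 chunk).
#' @param mode A single mode (`"A_W"`, `"M_W"`, `"A_CLS"`, `"M_CLS"`) or an
#'   ordered pair of two distinct modes, which concatenates their vectors.
#'   `A_W` is token-weighted: the mean runs over all tokens of all chunks, so
#'   the result does not depend on how the tokens were chunked.
#' @return Numeric document vector (length `dim`, or `2 * dim` for a pair).
#' @export
aggregate_document <- function(chunk_embeddings, mode) {
  if (length(chunk_embeddings) == 0) stop_bad("need at least one chunk")
  mode <- as.character(mode)
  valid <- c("A_W", "M_W", "A_CLS", "M_CLS")
  if (!all(mode %in% valid)) stop_bad("unknown aggregation mode")
  if (length(mode) == 2 && mode[1] == mode[2]) {
    stop_bad("concatenation modes must be distinct")
  }
  if (length(mode) > 2) stop_bad("mode must be one mode or an ordered pair")
  one <- function(m) {
    switch(m,
      A_W = {
        toks <- do.call(rbind, lapply(chunk_embeddings, `[[`, "tokens"))
        colMeans(toks)
      },
      M_W = {
        toks <- do.call(rbind, lapply(chunk_embeddings, `[[`, "tokens"))
        apply(toks, 2, max)
      },
      A_CLS = {
        cls <- do.call(rbind, lapply(chunk_embeddings, `[[`, "summary"))
        colMeans(cls)
      },
      M_CLS = {
        cls <- do.call(rbind, lapply(chunk_embeddings, `[[`, "summary"))
        apply(cls, 2, max)
      }
    )
  }
  unlist(lapply(mode, one), use.names = FALSE)
}

#' Embed a whole corpus
#'
#' Chunks each note's tokens at the backend's `max_chunk`, embeds every
#' chunk, and pools per [aggregate_document()]. Rows align with the corpus
#' note order. Notes with no tokens get a zero vector.
#'
#' @param backend An embedding backend (see [hash_embedding_backend()]).
#' @param corpus A [coded_corpus()].
#' @param mode Aggregation mode (single or ordered pair).
#' @return A [feature_matrix()].
#' @export
embed_corpus <- function(backend, corpus, mode = "A_W") {
  stopifnot(inherits(corpus, "coded_corpus"))
  out_dim <- backend$dim * length(mode)
  rows <- lapply(seq_along(corpus$tokens), function(i) {
    toks <- corpus$tokens[[i]]
    if (length(toks) == 0) return(numeric(out_dim))
    chunks <- chunk_tokens(toks, backend$max_chunk)
    embs <- tryCatch(
      lapply(chunks, backend$embed_chunk),
      error = function(e) {
        stop_bad("backend failed on note %s: %s", corpus$note_id[i], conditionMessage(e))
      }
    )
    aggregate_document(embs, mode)
  })
  feature_matrix(
    do.call(rbind, rows), corpus$note_id,
    sprintf("emb%03d", seq_len(out_dim)),
    provenance = list(family = "embedding", mode = paste(mode, collapse = "+"))
  )
}
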