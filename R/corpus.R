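# Coded-corpus container and IO: free-text notes carrying sets of procedure
# codes, a binary note x code label matrix, and deterministic tokenization.

#' Normalize raw note text into tokens
#'
#' Operative notes arrive with irregular casing, runs of whitespace and
#' non-ASCII artifacts from form-based editors. `preprocess_text()` lowercases
#' the text, strips all codepoints above 127, and returns the maximal runs of
#' `[a-z0-9]` as the token sequence. The map is deterministic and idempotent:
#' re-tokenizing the space-joined tokens reproduces them.
#'
#' @param text A single character string (NA is treated as empty).
#' @return Character vector of tokens (zero-length for empty input).
#' @examples
#' preprocess_text("Screw   REMOVED  deep.")
#' @export
preprocess_text <- function(text) {
  if (length(text) != 1) stop_bad("preprocess_text() expects a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("[^\x01-\x7f]", "", x, perl = TRUE, useBytes = TRUE)
  m <- gregexpr("[a-z0-9]+", x, perl = TRUE)
  toks <- regmatches(x, m)[[1]]
  if (length(toks) == 0) character(0) else toks
}

#' Construct a coded corpus
#'
#' Bundles notes, their token sequences and a binary note x code label matrix.
#' Column sums are cached as per-code counts. Every code must have at least
#' one positive note; duplicate note ids are rejected.
#'
#' @param note_id Character vector of unique note identifiers.
#' @param text Character vector of raw note texts (same length).
#' @param labels Binary matrix, `length(note_id)` rows, one column per code;
#'   column names are the code ids.
#' @return An object of class `coded_corpus` with elements `note_id`, `text`,
#'   `tokens` (list of character vectors), `codes`, `labels`, `counts`.
#' @export
coded_corpus <- function(note_id, text, labels) {
  note_id <- as.character(note_id)
  text <- as.character(text)
  if (length(note_id) != length(text)) stop_bad("note_id and text lengths differ")
  if (anyDuplicated(note_id)) {
    stop_bad("duplicate note_id: %s", note_id[duplicated(note_id)][1])
  }
  labels <- as.matrix(labels)
  if (nrow(labels) != length(note_id)) stop_bad("labels must have one row per note")
  if (is.null(colnames(labels))) stop_bad("labels must carry code ids as column names")
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels != 0L & labels != 1L)) {
    stop_bad("labels must be binary")
  }
  counts <- colSums(labels)
  if (sum(counts) == 0) stop_bad("no positive labels in corpus")
  if (any(counts == 0)) {
    stop_bad("code %s has no positive notes", colnames(labels)[counts == 0][1])
  }
  rownames(labels) <- note_id
  structure(
    list(
      note_id = note_id,
      text = text,
      tokens = lapply(text, preprocess_text),
      codes = colnames(labels),
      labels = labels,
      counts = counts
    ),
    class = "coded_corpus"
  )
}

#' @export
print.coded_corpus <- function(x, ...) {
  cat(sprintf(
    "coded_corpus: %d notes, %d codes, %d positive labels\n",
    length(x$note_id), length(x$codes), sum(x$counts)
  ))
  prev <- x$counts / length(x$note_id)
  cat(sprintf(
    "  prevalence range: %.3f%% - %.2f%%\n",
    100 * min(prev), 100 * max(prev)
  ))
  invisible(x)
}

#' Number of notes in a corpus
#' @param corpus A `coded_corpus`.
#' @return Integer count of notes.
#' @export
n_notes <- function(corpus) length(corpus$note_id)

#' Write a coded corpus as JSON Lines
#'
#' One JSON object per line with fields `note_id`, `text` and `codes` (the
#' list of code ids assigned to the note). This is the interchange format of
#' the package; label matrices are recoverable from the `codes` arrays.
#'
#' @param corpus A `coded_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "coded_corpus"))
  lines <- vapply(seq_along(corpus$note_id), function(i) {
    jsonlite::toJSON(
      list(
        note_id = jsonlite::unbox(corpus$note_id[i]),
        text = jsonlite::unbox(corpus$text[i]),
        codes = corpus$codes[corpus$labels[i, ] == 1L]
      ),
      auto_unbox = FALSE
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a coded corpus from JSON Lines
#'
#' Inverse of [write_corpus()] up to token recomputation and code ordering:
#' codes are ordered by descending positive count, ties broken by code id.
#' Unknown fields are ignored; a malformed line or a duplicated note id is an
#' error naming the offending line.
#'
#' @param path Path to a JSONL corpus file.
#' @return A `coded_corpus`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_bad("empty corpus file: %s", path)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) stop_bad("malformed JSON on line %d of %s", i, path)
    )
    if (is.null(rec$note_id) || is.null(rec$text)) {
      stop_bad("line %d of %s lacks note_id/text", i, path)
    }
    recs[[i]] <- rec
  }
  ids <- vapply(recs, function(r) as.character(r$note_id), character(1))
  if (anyDuplicated(ids)) {
    stop_bad(
      "duplicate note_id '%s' (line %d)",
      ids[duplicated(ids)][1], which(duplicated(ids))[1]
    )
  }
  texts <- vapply(recs, function(r) as.character(r$text), character(1))
  code_lists <- lapply(recs, function(r) as.character(unlist(r$codes)))
  all_codes <- sort(unique(unlist(code_lists)))
  if (length(all_codes) == 0) stop_bad("no positive labels in %s", path)
  labels <- matrix(0L, length(ids), length(all_codes),
    dimnames = list(ids, all_codes)
  )
  for (i in seq_along(code_lists)) {
    labels[i, code_lists[[i]]] <- 1L
  }
  # most-prevalent-first ordering; ties by code id
  counts <- colSums(labels)
  ord <- order(-counts, all_codes)
  coded_corpus(ids, texts, labels[, ord, drop = FALSE])
}

#' Keep only the most prevalent codes
#'
#' Mirrors restricting an analysis to the n most frequent codes in a corpus.
#' Notes are retained even if they end up with no positive label for the kept
#' code set. Ties in count are broken lexicographically by code id.
#'
#' @param corpus A `coded_corpus`.
#' @param n Number of codes to keep (1..number of codes).
#' @return A `coded_corpus` with `n` codes.
#' @export
select_top_codes <- function(corpus, n) {
  stopifnot(inherits(corpus, "coded_corpus"))
  if (!is_count(n)) stop_bad("n must be a positive integer")
  if (n > length(corpus$codes)) stop_bad("n exceeds the number of codes")
  ord <- order(-corpus$counts, corpus$codes)
  keep <- sort(ord[seq_len(n)]) # preserve existing column order
  out <- corpus
  out$labels <- corpus$labels[, keep, drop = FALSE]
  out$codes <- corpus$codes[keep]
  out$counts <- corpus$counts[keep]
  out
}

#' Write the binary label matrix as CSV
#'
#' @param corpus A `coded_corpus`.
#' @param path Output CSV path (note_id column plus one binary column per code).
#' @return `path`, invisibly.
#' @export
write_labels <- function(corpus, path) {
  df <- data.frame(note_id = corpus$note_id, corpus$labels,
    check.names = FALSE, row.names = NULL
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
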