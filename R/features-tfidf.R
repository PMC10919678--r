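# TF-IDF features with ANOVA F-value keyword selection.

#' Feature matrix container
#'
#' A plain numeric note x feature matrix plus alignment metadata and the
#' provenance of the extraction that produced it.
#'
#' @param values Numeric matrix (rows = notes).
#' @param note_ids Character vector, one per row.
#' @param feature_names Character vector, one per column.
#' @param provenance Named list describing family and configuration.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, note_ids, feature_names, provenance = list()) {
  values <- as.matrix(values)
  if (nrow(values) != length(note_ids)) stop_bad("row/note_id mismatch")
  if (ncol(values) != length(feature_names)) stop_bad("column/feature_name mismatch")
  if (any(!is.finite(values))) stop_bad("feature matrix contains non-finite values")
  dimnames(values) <- list(note_ids, feature_names)
  structure(
    list(
      values = values, note_ids = as.character(note_ids),
      feature_names = as.character(feature_names), provenance = provenance
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "feature_matrix: %d notes x %d features [%s]\n",
    nrow(x$values), ncol(x$values),
    paste(unlist(x$provenance), collapse = ", ")
  ))
  invisible(x)
}

#' Fit a TF-IDF model on training documents
#'
#' Vocabulary and document frequencies are learned from the training split
#' only; terms first seen at transform time are ignored. The weighting is the
#' smoothed convention: `idf(t) = ln((1 + N) / (1 + df(t))) + 1`, applied to
#' raw term counts and followed by L2 row normalization in
#' [transform_tfidf()].
#'
#' @param train_tokens List of token vectors (one per training document).
#' @return A `tfidf_model` with `vocabulary`, `document_frequency`,
#'   `n_train_docs`, `idf`.
#' @export
fit_tfidf <- function(train_tokens) {
  if (length(train_tokens) == 0) stop_bad("empty training corpus")
  vocab <- sort(unique(unlist(train_tokens)))
  if (length(vocab) == 0) stop_bad("training corpus has no tokens")
  df <- integer(length(vocab))
  names(df) <- vocab
  for (toks in train_tokens) {
    u <- unique(toks)
    df[u] <- df[u] + 1L
  }
  n <- length(train_tokens)
  structure(
    list(
      vocabulary = stats::setNames(seq_along(vocab), vocab),
      document_frequency = df,
      n_train_docs = n,
      idf = log((1 + n) / (1 + df)) + 1
    ),
    class = "tfidf_model"
  )
}

#' Transform documents into TF-IDF vectors
#'
#' @param model A [fit_tfidf()] model.
#' @param tokens List of token vectors.
#' @param note_ids Optional row ids (defaults to names of `tokens` or an
#'   index sequence).
#' @return A [feature_matrix()] with unit-L2 rows (all-zero rows for
#'   documents containing only unseen terms).
#' @export
transform_tfidf <- function(model, tokens, note_ids = NULL) {
  stopifnot(inherits(model, "tfidf_model"))
  note_ids <- note_ids %||% names(tokens) %||% sprintf("doc%d", seq_along(tokens))
  vocab <- names(model$vocabulary)
  trip <- lapply(seq_along(tokens), function(d) {
    j <- model$vocabulary[tokens[[d]]]
    j <- j[!is.na(j)]
    if (length(j) == 0) return(NULL)
    tab <- tabulate(j, nbins = length(vocab))
    nz <- which(tab > 0)
    list(i = rep.int(d, length(nz)), j = nz, x = tab[nz] * model$idf[nz])
  })
  trip <- trip[!vapply(trip, is.null, logical(1))]
  m <- Matrix::sparseMatrix(
    i = unlist(lapply(trip, `[[`, "i")) %||% integer(0),
    j = unlist(lapply(trip, `[[`, "j")) %||% integer(0),
    x = unlist(lapply(trip, `[[`, "x")) %||% numeric(0),
    dims = c(length(tokens), length(vocab))
  )
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  m <- as.matrix(m / norms)
  feature_matrix(m, note_ids, vocab, provenance = list(family = "tfidf", setting = "all"))
}

#' Per-feature one-way ANOVA F-values against a binary label
#'
#' For each column, the two-group F statistic
#' `(between-group SS / 1) / (within-group SS / (n - 2))`. Constant columns
#' get `F = 0`; columns with zero within-group variance but nonzero
#' between-group separation get `Inf`, which ranks above every finite value
#' in [select_features()].
#'
#' @param features A [feature_matrix()] or numeric matrix.
#' @param y Binary vector (0/1) with both classes present.
#' @return Named numeric vector of F-values (one per feature).
#' @export
anova_f <- function(features, y) {
  x <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop_bad("label length does not match rows")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop_bad("anova_f requires both classes present")
  n <- n1 + n0
  m1 <- colMeans(x[y == 1L, , drop = FALSE])
  m0 <- colMeans(x[y == 0L, , drop = FALSE])
  m <- (n1 * m1 + n0 * m0) / n
  between <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  within <- colSums((x[y == 1L, , drop = FALSE] - rep(m1, each = n1))^2) +
    colSums((x[y == 0L, , drop = FALSE] - rep(m0, each = n0))^2)
  f <- ifelse(within > 0, (between / 1) / (within / (n - 2)),
    ifelse(between > 0, Inf, 0)
  )
  # guard numerically-constant columns against spurious Inf
  f[between <= n * .Machine$double.eps^0.5 * 1e-8 & within == 0] <- 0
  stats::setNames(f, colnames(x))
}

#' Feature-selection configuration
#'
#' @param setting One of `"all"`, `"top100"`, `"top500"`, `"topK"`.
#' @param K Number of features kept when `setting = "topK"`.
#' @return A `selection_config`.
#' @export
selection_config <- function(setting = c("all", "top100", "top500", "topK"), K = NULL) {
  setting <- match.arg(setting)
  if (setting == "topK") {
    if (is.null(K) || !is_count(K)) stop_bad("topK requires a positive integer K")
  }
  structure(list(setting = setting, K = K), class = "selection_config")
}

#' Keep the features with highest ANOVA F-values
#'
#' Keeps the top `K` columns by F (100/500 for the fixed settings, all for
#' `"all"`), clipping `K` to the number of available features. Infinite
#' F-values sort above all finite ones; ties are broken by feature name.
#' Selected columns retain their original order.
#'
#' @param features A [feature_matrix()].
#' @param f_values Per-feature F-values, as from [anova_f()].
#' @param config A [selection_config()].
#' @return A [feature_matrix()] whose provenance records the setting.
#' @export
select_features <- function(features, f_values, config) {
  stopifnot(inherits(features, "feature_matrix"), inherits(config, "selection_config"))
  p <- ncol(features$values)
  k <- switch(config$setting,
    all = p, top100 = 100L, top500 = 500L, topK = config$K
  )
  k <- min(k, p)
  ord <- order(-f_values, features$feature_names)
  keep <- sort(ord[seq_len(k)])
  prov <- features$provenance
  prov$setting <- config$setting
  prov$K <- k
  feature_matrix(
    features$values[, keep, drop = FALSE],
    features$note_ids, features$feature_names[keep], prov
  )
}
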