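# Nearest-neighbour class-overlap complexity of a per-code task.
#
# In the feature space of the best-performing representation, a code is easy
# when its positive notes sit in tight, pure neighbourhoods: their nearest
# neighbours share the label (high same-label neighbour ratio) and lie close
# by relative to the corpus diameter (low normalized same-label radius). The
# two are combined as score = ln(distance / ratio): lower = simpler. The
# measure is invariant under rotation and uniform scaling of the space.

#' Complexity configuration
#'
#' @param neighbor_fraction Fraction of a code's positives that defines the
#'   neighbourhood size `M` (default 0.10, i.e. for a code with 4470
#'   positives, the 447 nearest notes).
#' @param strata_bounds Length-2 numeric `(low_upper, high_lower)`: scores
#'   below the first are "low" complexity, above the second "high",
#'   otherwise "medium". Defaults `(1, 2)`.
#' @return A `complexity_config`.
#' @export
complexity_config <- function(neighbor_fraction = 0.10, strata_bounds = c(1, 2)) {
  stopifnot(
    is.numeric(neighbor_fraction), neighbor_fraction > 0, neighbor_fraction <= 1,
    length(strata_bounds) == 2, strata_bounds[1] <= strata_bounds[2]
  )
  structure(
    list(neighbor_fraction = neighbor_fraction, strata_bounds = strata_bounds),
    class = "complexity_config"
  )
}

feature_values <- function(features) {
  if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
}

#' Same-label neighbour ratio of a code's positives
#'
#' For each positive note, its `M = max(1, round(neighbor_fraction * P))`
#' nearest notes by Euclidean distance (self excluded, `P` = positive count)
#' are found; the ratio is the fraction of those neighbours that are also
#' positive. Distance ties are broken by note index for a total,
#' reproducible ordering.
#'
#' @param features A [feature_matrix()] or numeric matrix over all notes.
#' @param y Binary labels (>= 2 positives).
#' @param config A [complexity_config()].
#' @param dist_matrix Optional precomputed full Euclidean distance matrix
#'   (avoids recomputation across codes).
#' @return List with `per_note` (ratio per positive) and `mean`.
#' @export
same_label_neighbor_ratio <- function(features, y, config = complexity_config(),
                                      dist_matrix = NULL) {
  x <- feature_values(features)
  y <- as.integer(y)
  pos <- which(y == 1L)
  P <- length(pos)
  if (P < 2) stop_bad("need at least 2 positive notes")
  M <- max(1L, as.integer(round(config$neighbor_fraction * P)))
  dmat <- dist_matrix %||% as.matrix(stats::dist(x))
  ratios <- vapply(pos, function(i) {
    d <- dmat[i, -i]
    idx <- seq_len(nrow(x))[-i]
    nb <- idx[order(d, idx)][seq_len(min(M, length(idx)))]
    mean(y[nb] == 1L)
  }, numeric(1))
  list(per_note = stats::setNames(ratios, rownames(x)[pos]), mean = mean(ratios))
}

#' Normalized same-label neighbour radius of a code's positives
#'
#' For each positive note, the radius of the smallest sphere containing its
#' `m = max(1, round(neighbor_fraction * (P - 1)))` nearest same-label
#' neighbours (self excluded), normalized by the corpus diameter (the
#' largest pairwise distance over ALL notes).
#'
#' @inheritParams same_label_neighbor_ratio
#' @return List with `per_note` (normalized radius per positive) and `mean`.
#' @export
same_label_neighbor_distance <- function(features, y, config = complexity_config(),
                                         dist_matrix = NULL) {
  x <- feature_values(features)
  y <- as.integer(y)
  pos <- which(y == 1L)
  P <- length(pos)
  if (P < 2) stop_bad("need at least 2 positive notes")
  m <- max(1L, as.integer(round(config$neighbor_fraction * (P - 1))))
  dmat <- dist_matrix %||% as.matrix(stats::dist(x))
  diameter <- max(dmat)
  if (diameter == 0) stop_bad("zero corpus diameter: all notes identical")
  radii <- vapply(pos, function(i) {
    d <- sort(dmat[i, setdiff(pos, i)])
    d[min(m, length(d))]
  }, numeric(1))
  radii <- radii / diameter
  list(per_note = stats::setNames(radii, rownames(x)[pos]), mean = mean(radii))
}

#' Combined complexity score
#'
#' `score = ln(distance / ratio)`. Lower scores mean the positives form
#' tighter, purer neighbourhoods and the code is easier to classify. Zero
#' inputs (duplicated notes, perfectly pure tiny neighbourhoods) are clamped
#' to `1 / (2 * n_notes)` so scores stay finite and ordered.
#'
#' @param ratio Mean same-label neighbour ratio in `(0, 1]`.
#' @param distance Mean normalized same-label radius in `(0, 1]`.
#' @param n_notes Corpus size used for the degenerate clamp (default 1000).
#' @return The score, a real number.
#' @export
complexity_score <- function(ratio, distance, n_notes = 1000) {
  clamp <- 1 / (2 * n_notes)
  if (distance == 0) distance <- clamp
  if (ratio == 0) ratio <- clamp
  log(distance / ratio)
}

#' Assign complexity strata
#'
#' @param score Numeric vector of complexity scores.
#' @param config A [complexity_config()]; scores below
#'   `strata_bounds[1]` are `"low"`, above `strata_bounds[2]` `"high"`,
#'   otherwise `"medium"`.
#' @return Character vector of strata.
#' @export
assign_strata <- function(score, config = complexity_config()) {
  b <- config$strata_bounds
  ifelse(score < b[1], "low", ifelse(score > b[2], "high", "medium"))
}

#' Complexity profile of every code in a corpus
#'
#' Runs the ratio, radius, combined score and stratum per code in the given
#' feature space (conventionally the space of the best-performing
#' representation).
#'
#' @param features A [feature_matrix()] over all notes.
#' @param corpus A [coded_corpus()] (or a binary label matrix with code
#'   columns).
#' @param config A [complexity_config()].
#' @return A `data.frame`: `code_id`, `ratio`, `distance`, `score`,
#'   `stratum`.
#' @export
complexity_profile <- function(features, corpus, config = complexity_config()) {
  labels <- if (inherits(corpus, "coded_corpus")) corpus$labels else as.matrix(corpus)
  n <- nrow(labels)
  dmat <- as.matrix(stats::dist(feature_values(features)))
  out <- lapply(colnames(labels), function(code) {
    y <- labels[, code]
    r <- same_label_neighbor_ratio(features, y, config, dist_matrix = dmat)$mean
    d <- same_label_neighbor_distance(features, y, config, dist_matrix = dmat)$mean
    s <- complexity_score(r, d, n_notes = n)
    data.frame(
      code_id = code, ratio = r, distance = d, score = s,
      stratum = assign_strata(s, config), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Variance in AUROC explained by the complexity score
#'
#' Ordinary least squares of per-code AUROC on the complexity score;
#' returns the adjusted R-squared `1 - (1 - R^2)(n - 1)/(n - 2)`.
#'
#' @param scores Per-code complexity scores (>= 3 codes, non-constant).
#' @param aurocs Per-code AUROC values.
#' @return List with `adj_r_squared`, `r_squared`, `slope`, `p_value`.
#' @export
variance_explained <- function(scores, aurocs) {
  stopifnot(length(scores) == length(aurocs))
  n <- length(scores)
  if (n < 3) stop_bad("need at least 3 codes")
  if (stats::sd(scores) == 0) stop_bad("constant complexity scores")
  fit <- stats::lm(aurocs ~ scores)
  sm <- summary(fit)
  list(
    adj_r_squared = sm$adj.r.squared,
    r_squared = sm$r.squared,
    slope = unname(stats::coef(fit)[2]),
    p_value = unname(sm$coefficients[2, 4])
  )
}
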