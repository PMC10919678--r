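# Per-code binary classification with an RBF-kernel SVM.
#
# One classifier per code: a stratified 20% test split, seeded
# hyperparameter search (C, gamma, and optionally the number K of
# ANOVA-F-selected keywords) scored by mean stratified k-fold
# cross-validated AUROC, then a final fit on the training split and
# evaluation on the held-out test notes. Class weights are inversely
# proportional to class frequency so codes at fractions of a percent
# prevalence still train.

#' Stratified train/test split
#'
#' Preserves the positive fraction: the test set gets `round(test_fraction *
#' P)` positives and `round(test_fraction * N)` negatives, chosen by a seeded
#' shuffle. Indices are disjoint and exhaustive.
#'
#' @param y Binary vector.
#' @param test_fraction Fraction in (0, 1), default 0.2.
#' @param seed Integer seed.
#' @param code_id Optional label used in error messages.
#' @return List with integer vectors `train` and `test`.
#' @export
stratified_split <- function(y, test_fraction = 0.2, seed = 1L, code_id = NULL) {
  y <- as.integer(y)
  lab <- if (is.null(code_id)) "" else sprintf(" for code %s", code_id)
  if (!(is.numeric(test_fraction) && test_fraction > 0 && test_fraction < 1)) {
    stop_bad("test_fraction must be in (0,1)%s", lab)
  }
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (length(pos) < 2 || length(neg) < 2) {
    stop_bad("both classes need at least 2 members%s (pos=%d, neg=%d)",
      lab, length(pos), length(neg)
    )
  }
  n_test_pos <- round(test_fraction * length(pos))
  n_test_neg <- round(test_fraction * length(neg))
  if (n_test_pos < 1 || n_test_pos >= length(pos)) {
    stop_bad("stratified split leaves no positives in train or test%s", lab)
  }
  with_seed(seed, {
    pos <- sample(pos); neg <- sample(neg)
    test <- c(pos[seq_len(n_test_pos)], neg[seq_len(n_test_neg)])
    train <- setdiff(c(pos, neg), test)
    list(train = sort(train), test = sort(test))
  })
}

# stratified fold assignment, seeded
stratified_folds <- function(y, folds, seed) {
  y <- as.integer(y)
  assign <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Hyperparameter search space
#'
#' Ranges are sampled log-uniformly: for `K` in particular the log-uniform
#' shape gives smaller keyword counts a higher chance, guarding against
#' overfitting large vocabularies.
#'
#' @param C_range,gamma_range Length-2 positive numeric ranges.
#' @param K_range Length-2 positive integer range, or `NULL` when the
#'   feature count is not tuned.
#' @param budget Number of evaluations.
#' @param folds Cross-validation folds (>= 2).
#' @return A `search_space`.
#' @export
search_space <- function(C_range = c(1e-2, 1e3), gamma_range = c(1e-4, 1e1),
                         K_range = NULL, budget = 50, folds = 5) {
  stopifnot(length(C_range) == 2, all(C_range > 0),
    length(gamma_range) == 2, all(gamma_range > 0),
    is_count(budget), is_count(folds), folds >= 2
  )
  if (!is.null(K_range)) {
    stopifnot(length(K_range) == 2, all(K_range >= 1))
  }
  structure(
    list(
      C_range = sort(C_range), gamma_range = sort(gamma_range),
      K_range = if (!is.null(K_range)) sort(round(K_range)),
      budget = as.integer(budget), folds = as.integer(folds)
    ),
    class = "search_space"
  )
}

# one RBF-SVM fit; returns a scorer giving oriented decision values
fit_rbf_svm <- function(x, y, C, gamma, code_id = NULL) {
  yf <- factor(y, levels = c(0L, 1L))
  n <- length(y)
  w <- c("0" = n / (2 * sum(y == 0L)), "1" = n / (2 * sum(y == 1L)))
  fit <- tryCatch(
    e1071::svm(
      x = x, y = yf, type = "C-classification", kernel = "radial",
      cost = C, gamma = gamma, class.weights = w, scale = FALSE
    ),
    error = function(e) {
      stop_bad(
        "SVM training failed%s: %s",
        if (is.null(code_id)) "" else sprintf(" for code %s", code_id),
        conditionMessage(e)
      )
    }
  )
  function(newx) {
    pr <- stats::predict(fit, newx, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # libsvm reports the margin for "first/second" in the column name;
    # orient so larger score = more positive
    flip <- identical(colnames(dv)[1], "0/1")
    score <- as.numeric(dv[, 1]) * if (flip) -1 else 1
    list(score = score, label = as.integer(as.character(pr)))
  }
}

# mean CV AUROC of one candidate; optionally refits top-K selection per fold
cv_objective <- function(x, y, C, gamma, K, folds_assign) {
  aucs <- vapply(sort(unique(folds_assign)), function(f) {
    tr <- which(folds_assign != f); va <- which(folds_assign == f)
    if (length(unique(y[va])) < 2 || length(unique(y[tr])) < 2) return(NA_real_)
    xtr <- x[tr, , drop = FALSE]; xva <- x[va, , drop = FALSE]
    if (!is.null(K)) {
      fv <- anova_f(xtr, y[tr])
      ord <- order(-fv, colnames(x))
      keep <- sort(ord[seq_len(min(K, ncol(x)))])
      xtr <- xtr[, keep, drop = FALSE]; xva <- xva[, keep, drop = FALSE]
    }
    scorer <- fit_rbf_svm(xtr, y[tr], C, gamma)
    auroc(y[va], scorer(xva)$score)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Tune SVM hyperparameters by seeded sequential search
#'
#' The objective is mean stratified k-fold cross-validated AUROC on the
#' training data. Candidates are drawn log-uniformly for the first half of
#' the budget, then sampled around the incumbent best (lognormal
#' perturbations, clipped to the ranges) — a simple seeded
#' exploration/exploitation schedule. When `space$K_range` is set, ANOVA-F
#' top-K selection is refit inside each training fold, so the tuned K never
#' sees validation labels. Returns the best evaluated point.
#'
#' @param features A [feature_matrix()] or numeric matrix (training rows).
#' @param y Binary training labels.
#' @param space A [search_space()].
#' @param seed Integer seed.
#' @return List with `params` (`C`, `gamma`, and `K` when tuned), `cv_auroc`,
#'   and `evaluations` (a data.frame of every point tried).
#' @export
tune_svm <- function(features, y, space = search_space(), seed = 1L) {
  x <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  y <- as.integer(y)
  stopifnot(inherits(space, "search_space"))
  folds_assign <- stratified_folds(y, space$folds, derive_seed(seed, 11))
  tune_k <- !is.null(space$K_range)
  kr <- if (tune_k) pmin(space$K_range, ncol(x))

  with_seed(derive_seed(seed, 12), {
    n_explore <- max(1, ceiling(space$budget / 2))
    evals <- vector("list", space$budget)
    best <- NULL
    draw_exploit <- function(best_par) {
      lC <- stats::rnorm(1, log(best_par$C), diff(log(space$C_range)) / 8)
      lg <- stats::rnorm(1, log(best_par$gamma), diff(log(space$gamma_range)) / 8)
      par <- list(
        C = exp(min(max(lC, log(space$C_range[1])), log(space$C_range[2]))),
        gamma = exp(min(max(lg, log(space$gamma_range[1])), log(space$gamma_range[2])))
      )
      if (tune_k) {
        lk <- stats::rnorm(1, log(best_par$K), diff(log(kr)) / 8)
        par$K <- as.integer(round(exp(min(max(lk, log(kr[1])), log(kr[2])))))
      }
      par
    }
    draw_uniform <- function() {
      par <- list(
        C = exp(stats::runif(1, log(space$C_range[1]), log(space$C_range[2]))),
        gamma = exp(stats::runif(1, log(space$gamma_range[1]), log(space$gamma_range[2])))
      )
      if (tune_k) {
        par$K <- as.integer(round(exp(stats::runif(1, log(kr[1]), log(kr[2])))))
      }
      par
    }
    for (b in seq_len(space$budget)) {
      par <- if (b <= n_explore || is.null(best)) draw_uniform() else draw_exploit(best$params)
      obj <- tryCatch(
        cv_objective(x, y, par$C, par$gamma, par$K, folds_assign),
        error = function(e) NA_real_
      )
      evals[[b]] <- data.frame(
        C = par$C, gamma = par$gamma, K = par$K %||% NA_integer_, cv_auroc = obj
      )
      if (!is.na(obj) && (is.null(best) || obj > best$cv_auroc)) {
        best <- list(params = par, cv_auroc = obj)
      }
    }
    if (is.null(best)) stop_bad("all hyperparameter evaluations failed")
    best$evaluations <- do.call(rbind, evals)
    best
  })
}

#' Train on the training split and evaluate on the test split
#'
#' Fits the RBF-SVM at the given parameters with inverse-frequency class
#' weights; when `params$K` is present, ANOVA-F top-K selection is fit on the
#' training split and applied to both splits. Predicted label is the sign of
#' the decision score; decision scores are retained for AUROC.
#'
#' @param features A [feature_matrix()] or matrix covering all notes.
#' @param y Binary labels for all notes.
#' @param split A [stratified_split()] result.
#' @param params List with `C`, `gamma`, optionally `K`.
#' @param code_id Optional code label carried into the result and errors.
#' @param cv_auroc Optional tuning objective to carry along.
#' @return A `classifier_result`: `code_id`, `params`, `metrics`,
#'   `test_scores`, `test_predictions`, `test_indices`, `cv_auroc`.
#' @export
train_and_evaluate <- function(features, y, split, params, code_id = NULL,
                               cv_auroc = NA_real_) {
  x <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  y <- as.integer(y)
  stopifnot(all(c("C", "gamma") %in% names(params)), params$C > 0, params$gamma > 0)
  tr <- split$train; te <- split$test
  xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
  if (!is.null(params$K)) {
    fv <- anova_f(xtr, y[tr])
    ord <- order(-fv, colnames(x))
    keep <- sort(ord[seq_len(min(params$K, ncol(x)))])
    xtr <- xtr[, keep, drop = FALSE]; xte <- xte[, keep, drop = FALSE]
  }
  scorer <- fit_rbf_svm(xtr, y[tr], params$C, params$gamma, code_id)
  out <- scorer(xte)
  structure(
    list(
      code_id = code_id, params = params,
      metrics = compute_metrics(y[te], out$score, out$label),
      test_scores = out$score, test_predictions = out$label,
      test_indices = te, cv_auroc = cv_auroc
    ),
    class = "classifier_result"
  )
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted one half; computed from midranks, so it matches exhaustive
#' pair counting exactly and is invariant under strictly monotone transforms
#' of the scores.
#'
#' @param y_true Binary vector with both classes present.
#' @param scores Numeric decision scores.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(y_true, scores) {
  y <- as.integer(y_true)
  P <- sum(y == 1L); N <- sum(y == 0L)
  if (P == 0 || N == 0) stop_bad("AUROC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - P * (P + 1) / 2) / (P * N)
}

#' Classification metrics at a fixed operating point
#'
#' @param y_true Binary vector (both classes required, for AUROC).
#' @param scores Decision scores.
#' @param predictions Predicted binary labels.
#' @return A `metrics` list: `auroc`, `accuracy`, `sensitivity`,
#'   `specificity`, and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
compute_metrics <- function(y_true, scores, predictions) {
  y <- as.integer(y_true); p <- as.integer(predictions)
  stopifnot(length(y) == length(scores), length(y) == length(p))
  tp <- sum(y == 1L & p == 1L); fn <- sum(y == 1L & p == 0L)
  tn <- sum(y == 0L & p == 0L); fp <- sum(y == 0L & p == 1L)
  structure(
    list(
      auroc = auroc(y, scores),
      accuracy = (tp + tn) / length(y),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      tp = tp, fp = fp, tn = tn, fn = fn
    ),
    class = "metrics"
  )
}
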