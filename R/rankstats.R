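# Rank-based comparison of methods across many per-code tasks.
#
# The comparison table is tasks (codes) in rows, methods in columns, holding
# per-task AUROC. Methods are ranked within each task (rank 1 = best), the
# Friedman test asks whether any method differs, pairwise exact Wilcoxon
# signed-rank tests with Holm step-down localize the differences, and
# critical-difference cliques group methods whose differences are not
# significant — the statistical content of a critical-difference diagram.

check_auroc_table <- function(auroc_table) {
  m <- as.matrix(auroc_table)
  if (ncol(m) < 2) stop_bad("need at least 2 methods (columns)")
  if (nrow(m) < 2) stop_bad("need at least 2 tasks (rows)")
  if (any(!is.finite(m))) stop_bad("auroc table contains non-finite entries")
  if (is.null(colnames(m))) colnames(m) <- sprintf("method%d", seq_len(ncol(m)))
  m
}

#' Average rank of each method across tasks
#'
#' Within each task (row) the best AUROC gets rank 1; ties share the mean
#' rank, so every row's ranks sum to `k(k+1)/2`.
#'
#' @param auroc_table Numeric matrix, tasks x methods.
#' @return Named numeric vector of average ranks.
#' @export
average_ranks <- function(auroc_table) {
  m <- check_auroc_table(auroc_table)
  ranks <- t(apply(m, 1, function(r) rank(-r, ties.method = "average")))
  colMeans(ranks)
}

#' Friedman test across methods
#'
#' Tie-corrected Friedman chi-square over within-task ranks, with `k - 1`
#' degrees of freedom; on tie-free tables it reduces to the classical
#' closed form. Identical columns give statistic 0 and p = 1. With only two
#' methods the chi-square form is not meaningful and the p-value is
#' delegated to the exact Wilcoxon signed-rank test (statistic reported as
#' NA).
#'
#' @param auroc_table Numeric matrix, tasks x methods (k >= 2, n >= 2).
#' @return List with `statistic`, `p_value`, `df`, `method`.
#' @export
friedman_rank_test <- function(auroc_table) {
  m <- check_auroc_table(auroc_table)
  n <- nrow(m); k <- ncol(m)
  if (k == 2) {
    p <- wilcoxon_signed_rank(m[, 1] - m[, 2])$p_value
    return(list(statistic = NA_real_, p_value = p, df = NA_integer_,
      method = "wilcoxon signed-rank (k = 2)"
    ))
  }
  ranks <- t(apply(m, 1, function(r) rank(-r, ties.method = "average")))
  Rj <- colSums(ranks)
  num <- (k - 1) * (sum(Rj^2) - n^2 * k * (k + 1)^2 / 4)
  den <- sum(ranks^2) - n * k * (k + 1)^2 / 4
  if (den <= 0) {
    return(list(statistic = 0, p_value = 1, df = k - 1L, method = "friedman"))
  }
  stat <- num / den
  list(
    statistic = stat,
    p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
    df = k - 1L, method = "friedman"
  )
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (Wilcoxon's original treatment). For up to
#' `exact_max` nonzero differences the p-value is exact: the null
#' distribution of the positive-rank sum is built over all 2^n equiprobable
#' sign assignments (conditioning on the observed midranks, so ties are
#' handled exactly). Larger samples use the normal approximation with tie
#' correction and continuity correction. All differences zero gives p = 1.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_max Largest n for the exact null (default 25).
#' @return List with `statistic` (positive-rank sum `W`), `n_nonzero`,
#'   `p_value`, `exact`.
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 25) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, n_nonzero = 0L, p_value = 1, exact = TRUE))
  }
  r <- rank(abs(d), ties.method = "average")
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution over doubled ranks (integers even under midrank ties)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dp <- numeric(total + 1)
    dp[1] <- 1
    for (rv in r2) {
      shifted <- c(numeric(rv), dp[seq_len(total + 1 - rv)])
      dp <- dp + shifted
    }
    dp <- dp / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(dp[seq_len(w2 + 1)])
    p_ge <- sum(dp[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = W, n_nonzero = as.integer(n), p_value = p, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(statistic = W, n_nonzero = as.integer(n), p_value = p, exact = FALSE)
  }
}

#' Pairwise Wilcoxon signed-rank tests with Holm step-down adjustment
#'
#' All `k(k-1)/2` method pairs are tested two-sided on per-task AUROC
#' differences; the raw p-values are Holm-adjusted (sort ascending, multiply
#' the i-th by `m - i + 1`, take the running maximum, cap at 1). A pair with
#' all-zero differences records p = 1.
#'
#' @param auroc_table Numeric matrix, tasks x methods.
#' @param alpha Significance level carried in the result (default 0.05).
#' @return List with `p_matrix` (symmetric, unit diagonal, Holm-adjusted),
#'   `raw_p`, and `alpha`.
#' @export
wilcoxon_holm <- function(auroc_table, alpha = 0.05) {
  m <- check_auroc_table(auroc_table)
  k <- ncol(m)
  pairs <- utils::combn(k, 2)
  raw <- apply(pairs, 2, function(ij) {
    wilcoxon_signed_rank(m[, ij[1]] - m[, ij[2]])$p_value
  })
  adj <- holm_adjust(raw)
  pm <- diag(1, k)
  dimnames(pm) <- list(colnames(m), colnames(m))
  for (q in seq_len(ncol(pairs))) {
    pm[pairs[1, q], pairs[2, q]] <- adj[q]
    pm[pairs[2, q], pairs[1, q]] <- adj[q]
  }
  list(p_matrix = pm, raw_p = stats::setNames(
    raw, apply(pairs, 2, function(ij) paste(colnames(m)[ij], collapse = " vs "))
  ), alpha = alpha)
}

#' Holm step-down adjustment
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order (monotone, >= raw,
#'   capped at 1).
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- cummax((m - seq_len(m) + 1) * p[ord])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Critical-difference cliques
#'
#' Orders methods by average rank (best first) and reports the maximal
#' rank-contiguous groups of two or more methods whose internal pairwise
#' adjusted p-values all exceed `alpha` — the groups a critical-difference
#' diagram joins with a horizontal bar. No reported clique is contained in
#' another; if every pair differs significantly, each method is its own
#' clique.
#'
#' @param avg_ranks Named average ranks, as from [average_ranks()].
#' @param adjusted_p Symmetric Holm-adjusted p-value matrix.
#' @param alpha Significance level.
#' @return List with `order` (method names, best first) and `cliques`
#'   (list of character vectors).
#' @export
cd_cliques <- function(avg_ranks, adjusted_p, alpha = 0.05) {
  methods <- names(avg_ranks)
  stopifnot(!is.null(methods), all(methods %in% rownames(adjusted_p)))
  ord <- methods[order(avg_ranks, methods)]
  k <- length(ord)
  ns <- function(a, b) adjusted_p[a, b] > alpha
  cliques <- list()
  i <- 1
  while (i <= k) {
    j <- i
    while (j < k && all(vapply((i:j), function(q) ns(ord[q], ord[j + 1]), logical(1)))) {
      j <- j + 1
    }
    if (j > i) cliques[[length(cliques) + 1]] <- ord[i:j]
    i <- i + 1
  }
  # drop cliques contained in an earlier, larger one
  if (length(cliques) > 1) {
    keep <- rep(TRUE, length(cliques))
    for (a in seq_along(cliques)) {
      for (b in seq_along(cliques)) {
        if (a != b && keep[a] && all(cliques[[a]] %in% cliques[[b]]) &&
          length(cliques[[a]]) < length(cliques[[b]])) {
          keep[a] <- FALSE
        }
      }
    }
    cliques <- cliques[keep]
  }
  if (length(cliques) == 0) cliques <- as.list(ord)
  list(order = ord, cliques = cliques)
}

#' Full method comparison
#'
#' Assembles average ranks, the Friedman test, Holm-adjusted pairwise
#' Wilcoxon signed-rank p-values, and critical-difference cliques for a
#' tasks x methods AUROC table.
#'
#' @param auroc_table Numeric matrix, tasks x methods.
#' @param alpha Significance level (default 0.05).
#' @return A `method_comparison` list: `auroc_table`, `avg_ranks`,
#'   `friedman`, `pairwise_p`, `cliques`, `alpha`.
#' @export
method_comparison <- function(auroc_table, alpha = 0.05) {
  m <- check_auroc_table(auroc_table)
  ar <- average_ranks(m)
  wh <- wilcoxon_holm(m, alpha)
  cl <- cd_cliques(ar, wh$p_matrix, alpha)
  structure(
    list(
      auroc_table = m, avg_ranks = ar,
      friedman = friedman_rank_test(m),
      pairwise_p = wh$p_matrix, raw_p = wh$raw_p,
      cliques = cl$cliques, method_order = cl$order, alpha = alpha
    ),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("method_comparison over", nrow(x$auroc_table), "tasks\n")
  cat("  average ranks (1 = best):\n")
  ar <- sort(x$avg_ranks)
  for (m in names(ar)) cat(sprintf("    %-24s %.3f\n", m, ar[m]))
  if (!is.na(x$friedman$statistic)) {
    cat(sprintf(
      "  Friedman chi-sq = %.3f (df %d), p = %.3g\n",
      x$friedman$statistic, x$friedman$df, x$friedman$p_value
    ))
  } else {
    cat(sprintf("  two-method comparison, Wilcoxon p = %.3g\n", x$friedman$p_value))
  }
  for (cl in x$cliques) {
    if (length(cl) > 1) cat("  no significant difference:", paste(cl, collapse = " ~ "), "\n")
  }
  invisible(x)
}

#' Plot a critical-difference diagram
#'
#' Methods on a rank axis (best to the right), with horizontal bars joining
#' cliques of methods whose AUROC differences are not significant.
#'
#' @param comparison A [method_comparison()].
#' @param ... Passed to [graphics::plot()].
#' @return The comparison, invisibly.
#' @export
plot_cd_diagram <- function(comparison, ...) {
  stopifnot(inherits(comparison, "method_comparison"))
  ar <- comparison$avg_ranks
  k <- length(ar)
  graphics::plot(NULL,
    xlim = rev(range(c(1, k, ar))), ylim = c(0, k + 1), xlab = "average rank",
    ylab = "", yaxt = "n", main = "Critical difference diagram", ...
  )
  ord <- comparison$method_order
  ys <- stats::setNames(seq_along(ord), ord)
  for (m in ord) {
    graphics::points(ar[m], ys[m], pch = 19)
    graphics::text(ar[m], ys[m], sprintf("%s (%.2f)", m, ar[m]), pos = 3, cex = 0.8)
  }
  i <- 0
  for (cl in comparison$cliques) {
    if (length(cl) < 2) next
    i <- i + 1
    graphics::segments(min(ar[cl]), k + 0.5 - 0.2 * i, max(ar[cl]), k + 0.5 - 0.2 * i, lwd = 4)
  }
  invisible(comparison)
}
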