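test_that("average ranks follow the hand-worked example and sum rule", {
  tab <- rbind(c(0.9, 0.8), c(0.8, 0.9), c(0.7, 0.95))
  colnames(tab) <- c("A", "B")
  ar <- average_ranks(tab)
  expect_equal(unname(ar), c(mean(c(1, 2, 2)), mean(c(2, 1, 1))))

  twocol <- cbind(A = c(0.9, 0.9), B = c(0.5, 0.4))
  expect_equal(unname(average_ranks(twocol)), c(1, 2))

  same <- cbind(A = c(0.7, 0.8), B = c(0.7, 0.8), C = c(0.7, 0.8))
  expect_equal(unname(average_ranks(same)), rep(2, 3)) # (k+1)/2 under full ties

  # per-task rank sums are k(k+1)/2 whatever the ties
  set.seed(31)
  m <- matrix(sample(seq(0.5, 1, 0.05), 40, replace = TRUE), 8, 5)
  ranks <- t(apply(m, 1, function(r) rank(-r)))
  expect_true(all(rowSums(ranks) == 15))

  expect_error(average_ranks(cbind(A = c(1, NA), B = c(0, 1))), "non-finite")
})

test_that("friedman statistic matches the closed form on tie-free tables", {
  # one method always 1st, one 2nd, one 3rd over n = 5 tasks -> chi^2 = 10
  tab <- matrix(rep(c(0.9, 0.8, 0.7), 5), 5, 3, byrow = TRUE)
  colnames(tab) <- c("A", "B", "C")
  ft <- friedman_rank_test(tab)
  expect_equal(ft$statistic, 10, tolerance = 1e-10)
  expect_equal(ft$p_value, pchisq(10, 2, lower.tail = FALSE))

  # closed form on random tie-free tables
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(4:10, 1); k <- sample(3:6, 1)
    m <- matrix(rnorm(n * k), n, k)
    colnames(m) <- sprintf("m%d", 1:k)
    ranks <- t(apply(m, 1, function(r) rank(-r)))
    Rj <- colSums(ranks)
    closed <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
    expect_equal(friedman_rank_test(m)$statistic, closed, tolerance = 1e-10)
    # permuting task order changes nothing
    expect_equal(
      friedman_rank_test(m[sample(n), ])$statistic,
      friedman_rank_test(m)$statistic,
      tolerance = 1e-12
    )
  }

  same <- matrix(0.8, 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  ft0 <- friedman_rank_test(same)
  expect_equal(ft0$statistic, 0)
  expect_equal(ft0$p_value, 1)
  expect_error(friedman_rank_test(matrix(1, 1, 3)), "2 tasks")
})

test_that("exact signed-rank p matches full sign enumeration", {
  # all five differences positive: two-sided p = 2/32
  expect_equal(wilcoxon_signed_rank(rep(0.1, 5) + (1:5) / 100)$p_value, 2 / 32)
  # all differences zero -> p = 1
  expect_equal(wilcoxon_signed_rank(rep(0, 4))$p_value, 1)
  set.seed(23)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    d <- round(rnorm(n), 1) # rounding forces ties and zeros
    expect_equal(
      wilcoxon_signed_rank(d)$p_value,
      oracle_signed_rank_p(d),
      tolerance = 1e-12,
      info = paste("d =", paste(d, collapse = ","))
    )
  }
  # agrees with the reference implementation when no ties/zeros
  d <- c(0.3, -0.11, 0.52, 0.27, -0.04, 0.19, 0.33)
  expect_equal(
    wilcoxon_signed_rank(d)$p_value,
    wilcox.test(d, exact = TRUE)$p.value,
    tolerance = 1e-12
  )
})

test_that("holm adjustment matches the hand-worked case and its guarantees", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(c(0.04, 0.01, 0.02)), c(0.04, 0.03, 0.04))
  set.seed(3)
  p <- runif(10)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(order(adj[order(p)]), seq_along(p)) # monotone in raw order
})

test_that("wilcoxon_holm returns a symmetric adjusted matrix with unit diagonal", {
  set.seed(5)
  tab <- cbind(
    A = runif(8, 0.8, 1), B = runif(8, 0.6, 0.8), C = runif(8, 0.55, 0.75)
  )
  wh <- wilcoxon_holm(tab)
  expect_equal(wh$p_matrix, t(wh$p_matrix))
  expect_equal(unname(diag(wh$p_matrix)), rep(1, 3))
  expect_true(all(wh$p_matrix >= 0 & wh$p_matrix <= 1))
  # identical methods: all adjusted p = 1
  same <- cbind(A = 1:5 / 10, B = 1:5 / 10, C = 1:5 / 10)
  expect_true(all(wilcoxon_holm(same)$p_matrix == 1))
})

test_that("cd_cliques groups non-significant rank-contiguous methods", {
  ar <- c(A = 1.0, B = 2.0, C = 3.0)
  sig_all <- matrix(0.001, 3, 3, dimnames = list(names(ar), names(ar)))
  diag(sig_all) <- 1
  cl <- cd_cliques(ar, sig_all, 0.05)
  expect_equal(cl$cliques, list("A", "B", "C")) # all significant -> singletons

  none <- matrix(0.9, 3, 3, dimnames = list(names(ar), names(ar)))
  diag(none) <- 1
  expect_equal(cd_cliques(ar, none, 0.05)$cliques, list(c("A", "B", "C")))

  # only the (2nd, 3rd) pair non-significant
  mix <- sig_all
  mix["B", "C"] <- mix["C", "B"] <- 0.4
  expect_equal(cd_cliques(ar, mix, 0.05)$cliques, list(c("B", "C")))
})

test_that("method_comparison bundles a coherent record", {
  set.seed(8)
  tab <- cbind(
    best = runif(10, 0.9, 1), mid = runif(10, 0.7, 0.9), worst = runif(10, 0.5, 0.7)
  )
  mc <- method_comparison(tab)
  expect_s3_class(mc, "method_comparison")
  expect_equal(mc$method_order[1], "best")
  expect_lt(mc$friedman$p_value, 0.05)
  expect_true(all(vapply(
    mc$cliques,
    function(cl) all(cl %in% colnames(tab)), logical(1)
  )))
  expect_output(print(mc), "average ranks")
})
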