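test_that("neighbor ratio matches hand-worked 1-D geometries", {
  x <- matrix(c(0.0, 0.1, 0.2, 10, 11, 12), ncol = 1)
  y <- c(1, 1, 1, 0, 0, 0)
  out <- same_label_neighbor_ratio(x, y) # P=3 -> M=1
  expect_equal(out$mean, 1.0)

  inter <- matrix(0:7, ncol = 1)
  y_int <- rep(c(1, 0), 4)
  expect_equal(same_label_neighbor_ratio(inter, y_int)$mean, 0) # alternating, M=1

  all_pos <- matrix(rnorm(10), ncol = 1)
  expect_equal(same_label_neighbor_ratio(all_pos, rep(1, 10))$mean, 1)
  expect_error(same_label_neighbor_ratio(x, c(1, rep(0, 5))), "2 positive")
})

test_that("neighbor distance matches hand-worked geometry and invariances", {
  x <- matrix(c(0.0, 0.1, 10), ncol = 1)
  y <- c(1, 1, 0)
  out <- same_label_neighbor_distance(x, y) # m=1, radii 0.1, diameter 10
  expect_equal(out$mean, 0.01)
  # uniform scaling leaves the normalized radius unchanged
  out_scaled <- same_label_neighbor_distance(x * 37.5, y)
  expect_equal(out_scaled$mean, out$mean, tolerance = 1e-12)
  # duplicated positives -> zero radius, clamped downstream
  dup <- matrix(c(0, 0, 5), ncol = 1)
  expect_equal(same_label_neighbor_distance(dup, y)$mean, 0)
  expect_equal(complexity_score(1, 0, n_notes = 100), log(1 / 200))
  expect_error(
    same_label_neighbor_distance(matrix(0, 3, 1), y),
    "diameter"
  )
})

test_that("both measures equal the brute-force oracle on random instances", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(30:200, 1)
    d <- sample(2:5, 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- rbinom(n, 1, runif(1, 0.15, 0.5))
    if (sum(y) < 3) next
    expect_identical(
      same_label_neighbor_ratio(x, y)$mean,
      oracle_ratio(x, y)
    )
    expect_identical(
      same_label_neighbor_distance(x, y)$mean,
      oracle_distance(x, y)
    )
  }
})

test_that("complexity score combines ratio and radius on the log scale", {
  expect_equal(complexity_score(1, 1), 0)
  expect_equal(complexity_score(0.5, 1), log(2))
  expect_equal(complexity_score(1, exp(-1)), -1)
})

test_that("strata follow the configured bounds", {
  cfg <- complexity_config()
  expect_equal(assign_strata(0.5, cfg), "low")
  expect_equal(assign_strata(1.5, cfg), "medium")
  expect_equal(assign_strata(2.69, cfg), "high")
  expect_equal(
    assign_strata(c(-0.4, 1, 2, 3), cfg),
    c("low", "medium", "medium", "high")
  )
})

test_that("measure is invariant under rotation and scaling, and tracks separation", {
  set.seed(71)
  n <- 80
  x <- cbind(rnorm(n), rnorm(n))
  y <- rbinom(n, 1, 0.4)
  y[1:3] <- 1
  base_r <- same_label_neighbor_ratio(x, y)$mean
  base_d <- same_label_neighbor_distance(x, y)$mean
  theta <- 0.77
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  xr <- 3.1 * x %*% rot
  expect_equal(same_label_neighbor_ratio(xr, y)$mean, base_r, tolerance = 1e-12)
  expect_equal(same_label_neighbor_distance(xr, y)$mean, base_d, tolerance = 1e-12)

  # translating positives away from negatives makes the task simpler
  scores <- sapply(c(0, 2, 6), function(shift) {
    x2 <- x
    x2[y == 1, 1] <- x2[y == 1, 1] + shift
    complexity_score(
      same_label_neighbor_ratio(x2, y)$mean,
      same_label_neighbor_distance(x2, y)$mean,
      n_notes = n
    )
  })
  expect_true(all(diff(scores) < 0))
})

test_that("complexity_profile labels every code and variance_explained is sane", {
  g <- separable_corpus(n = 120, n_codes = 4, seed = 19)
  corp <- g$corpus
  m <- fit_tfidf(corp$tokens)
  fm <- transform_tfidf(m, corp$tokens, corp$note_id)
  prof <- complexity_profile(fm, corp)
  expect_equal(prof$code_id, corp$codes)
  expect_true(all(prof$ratio > 0 & prof$ratio <= 1))
  expect_true(all(prof$distance > 0 & prof$distance <= 1))
  expect_equal(prof$score, log(prof$distance / prof$ratio))

  # exact linear relation -> adjusted R^2 = 1
  ve <- suppressWarnings(variance_explained(c(1, 2, 3), c(0.9, 0.8, 0.7)))
  expect_equal(ve$adj_r_squared, 1)
  # permuted scores explain nothing (checked loosely, one draw)
  set.seed(4)
  s <- rnorm(100)
  a <- 0.9 - 0.1 * s + rnorm(100, sd = 0.01)
  expect_gt(variance_explained(s, a)$adj_r_squared, 0.9)
  expect_lt(variance_explained(sample(s), a)$adj_r_squared, 0.1)
  expect_error(variance_explained(rep(1, 5), rnorm(5)), "constant")
})
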