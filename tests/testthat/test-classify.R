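test_that("stratified_split preserves the positive fraction and is seeded", {
  y <- c(rep(1, 10), rep(0, 90))
  sp <- stratified_split(y, 0.2, seed = 3)
  expect_equal(sum(y[sp$test]), 2)
  expect_equal(length(sp$test), 20)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_identical(sp, stratified_split(y, 0.2, seed = 3))
  expect_false(identical(sp, stratified_split(y, 0.2, seed = 4)))
  expect_error(stratified_split(y, 0), "test_fraction")
  expect_error(stratified_split(c(1, rep(0, 20)), 0.2, code_id = "X"), "X")
})

test_that("auroc equals exhaustive pair counting on random instances", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auroc(c(0, 1), c(0, 1)), 1)
  expect_equal(auroc(c(0, 1, 0, 1), rep(2, 4)), 0.5)
  expect_error(auroc(c(1, 1), c(0, 1)), "one class")
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(5:50, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(n), 2)) # coarse scores force ties
    expect_equal(auroc(y, s), oracle_auroc(y, s), tolerance = 1e-12)
  }
})

test_that("auroc is invariant under strictly monotone score transforms", {
  set.seed(12)
  y <- rbinom(40, 1, 0.3)
  y[1] <- 1; y[2] <- 0
  s <- rnorm(40)
  a <- auroc(y, s)
  expect_equal(auroc(y, exp(s)), a, tolerance = 1e-12)
  expect_equal(auroc(y, 3 * s - 7), a, tolerance = 1e-12)
  expect_equal(auroc(y, rank(s)), a, tolerance = 1e-12)
})

test_that("compute_metrics is consistent with its confusion counts", {
  set.seed(9)
  y <- rbinom(60, 1, 0.4); y[1:2] <- c(0, 1)
  s <- rnorm(60)
  p <- as.integer(s > 0)
  m <- compute_metrics(y, s, p)
  expect_equal(m$accuracy, (m$tp + m$tn) / 60)
  expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
  expect_equal(m$specificity, m$tn / (m$tn + m$fp))
  expect_true(all(unlist(m[c("auroc", "accuracy", "sensitivity", "specificity")]) >= 0))
})

test_that("svm pipeline achieves perfect test metrics on a separable fixture", {
  g <- separable_corpus(n = 150, n_codes = 2, seed = 31)
  corp <- g$corpus
  code <- corp$codes[1]
  y <- corp$labels[, code]
  m <- fit_tfidf(corp$tokens)
  fm <- transform_tfidf(m, corp$tokens, corp$note_id)
  f <- anova_f(fm, y)
  x <- select_features(fm, f, selection_config("topK", K = 12))
  split <- stratified_split(y, 0.2, seed = 1)
  res <- train_and_evaluate(x, y, split, list(C = 10, gamma = 1), code_id = code)
  expect_equal(res$metrics$auroc, 1)
  expect_equal(res$metrics$sensitivity, 1)

  # identical test rows receive identical scores (deterministic scorer)
  i_pos <- split$test[y[split$test] == 1][1]
  i_neg <- split$test[y[split$test] == 0][1]
  dup_split <- list(train = split$train, test = c(i_pos, i_neg, i_pos))
  dup <- train_and_evaluate(x, y, dup_split, list(C = 10, gamma = 1))
  expect_equal(dup$test_scores[1], dup$test_scores[3])
})

test_that("tuning returns the best evaluated point and hits 1.0 when separable", {
  g <- separable_corpus(n = 150, n_codes = 2, seed = 37)
  corp <- g$corpus
  y <- corp$labels[, 1]
  m <- fit_tfidf(corp$tokens)
  fm <- transform_tfidf(m, corp$tokens, corp$note_id)
  sp <- search_space(budget = 5, folds = 3, K_range = c(10, 200))
  tuned <- tune_svm(fm, y, sp, seed = 2)
  expect_equal(nrow(tuned$evaluations), 5)
  expect_equal(tuned$cv_auroc, max(tuned$evaluations$cv_auroc, na.rm = TRUE))
  expect_equal(tuned$cv_auroc, 1.0)
  # determinism
  tuned2 <- tune_svm(fm, y, sp, seed = 2)
  expect_identical(tuned$params, tuned2$params)
  # degenerate point space returns that point
  pt <- search_space(
    C_range = c(1, 1), gamma_range = c(0.5, 0.5),
    budget = 1, folds = 3
  )
  t3 <- tune_svm(fm, y, pt, seed = 5)
  expect_equal(t3$params$C, 1)
  expect_equal(t3$params$gamma, 0.5)
})

test_that("AUROC stays near chance when labels are independent of features", {
  g <- separable_corpus(n = 500, n_codes = 2, seed = 41)
  corp <- g$corpus
  m <- fit_tfidf(corp$tokens)
  fm <- transform_tfidf(m, corp$tokens, corp$note_id)
  set.seed(99)
  aucs <- replicate(5, {
    y_perm <- sample(corp$labels[, 1])
    split <- stratified_split(y_perm, 0.2, seed = sample.int(1e6, 1))
    res <- train_and_evaluate(fm, y_perm, split, list(C = 1, gamma = 0.01))
    res$metrics$auroc
  })
  # null AUROC concentrates around 0.5; allow one excursion
  expect_gte(mean(aucs > 0.3 & aucs < 0.7), 0.8)
})

test_that("class weighting keeps separable sensitivity at low prevalence", {
  for (prev in c(0.10, 0.05)) {
    specs <- make_code_specs(2,
      prevalence_range = c(prev, 4 * prev),
      ambiguity = 0, signature_emission_prob = 1
    )
    cfg <- generator_config(400, specs,
      misspell_rate = 0, whitespace_noise_rate = 0,
      nonascii_rate = 0, seed = 53
    )
    corp <- generate_corpus(cfg)$corpus
    code <- corp$codes[2] # the rarer one
    y <- corp$labels[, code]
    m <- fit_tfidf(corp$tokens)
    fm <- transform_tfidf(m, corp$tokens, corp$note_id)
    f <- anova_f(fm, y)
    x <- select_features(fm, f, selection_config("topK", K = 12))
    split <- stratified_split(y, 0.2, seed = 1)
    res <- train_and_evaluate(x, y, split, list(C = 10, gamma = 1))
    expect_equal(res$metrics$sensitivity, 1)
  }
})
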