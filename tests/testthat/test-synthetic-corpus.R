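# The generator is the package's stand-in for a real operative-note corpus;
# these tests pin down its statistical contract.

test_that("same config and seed give byte-identical corpora and truth", {
  specs <- make_code_specs(4, prevalence_range = c(0.1, 0.3), ambiguity = 0.5)
  cfg <- generator_config(120, specs, label_flip_rate = 0.05, seed = 42)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(g1$corpus$text, g2$corpus$text)
  expect_identical(g1$corpus$labels, g2$corpus$labels)
  expect_identical(g1$truth, g2$truth)
})

test_that("observed clean prevalence tracks the configured rate within 3 binomial sigma", {
  # enough total prevalence mass that the 1-3-codes-per-note repair is rare
  specs <- c(
    make_code_specs(1, prevalence_range = c(0.10, 0.10)),
    lapply(2:7, function(j) {
      code_spec(sprintf("3%04d", j), 0.3, paste0("sigterm", j, letters[1:4]))
    })
  )
  cfg <- generator_config(1000, specs, seed = 9)
  g <- generate_corpus(cfg)
  counts <- colSums(g$truth$clean_labels)
  expect_lt(abs(counts[1] - 100), 3 * sqrt(1000 * 0.1 * 0.9)) # ~ +/- 29
  for (j in 2:7) {
    expect_lt(abs(counts[j] - 300), 3 * sqrt(1000 * 0.3 * 0.7))
  }
})

test_that("every note carries 1-3 codes and flips are one-sided", {
  g <- separable_corpus(n = 200, n_codes = 5, seed = 3)
  rs <- rowSums(g$truth$clean_labels)
  expect_true(all(rs >= 1 & rs <= 3))

  specs <- make_code_specs(3, prevalence_range = c(0.15, 0.3))
  cfg <- generator_config(400, specs, label_flip_rate = 0.1, seed = 5)
  g2 <- generate_corpus(cfg)
  diff <- g2$truth$clean_labels - g2$corpus$labels
  expect_true(all(diff >= 0)) # only positive -> negative
  expect_equal(nrow(g2$truth$flips), sum(diff))
  # flip volume within 3 binomial sd of the rate
  n_pos <- sum(g2$truth$clean_labels)
  expect_lt(
    abs(nrow(g2$truth$flips) - 0.1 * n_pos),
    3 * sqrt(n_pos * 0.1 * 0.9)
  )
})

test_that("zero flip rate changes nothing", {
  g <- separable_corpus(n = 80, n_codes = 3, seed = 8)
  expect_identical(g$corpus$labels, g$truth$clean_labels)
  expect_equal(nrow(g$truth$flips), 0)
})

test_that("inject_label_noise honors its rate contract", {
  labels <- matrix(rbinom(500 * 4, 1, 0.5), 500, 4,
    dimnames = list(sprintf("n%d", 1:500), c("a", "b", "c", "d"))
  )
  storage.mode(labels) <- "integer"
  out0 <- notecodify:::with_seed(1, inject_label_noise(labels, 0))
  expect_equal(nrow(out0$flips), 0)
  expect_identical(out0$labels, labels)

  out1 <- notecodify:::with_seed(1, inject_label_noise(labels, 1))
  expect_equal(sum(out1$labels), 0)
  expect_equal(nrow(out1$flips), sum(labels))

  n_pos <- sum(labels)
  out <- notecodify:::with_seed(7, inject_label_noise(labels, 0.02))
  expect_lt(abs(nrow(out$flips) - 0.02 * n_pos), 3 * sqrt(n_pos * 0.02 * 0.98))
})

test_that("corrupt_text honors rate contracts", {
  specs <- make_code_specs(2, prevalence_range = c(0.2, 0.3))
  mk <- function(...) generator_config(100, specs, seed = 1, ...)
  txt <- "the implant was removed. deep screw extracted. wound closed."

  clean <- mk(misspell_rate = 0, whitespace_noise_rate = 0, nonascii_rate = 0)
  expect_identical(corrupt_text(txt, clean), txt)

  # misspell_rate = 1: every word ends at edit distance exactly 1
  sp <- mk(misspell_rate = 1, whitespace_noise_rate = 0, nonascii_rate = 0)
  out <- notecodify:::with_seed(2, corrupt_text("screw implant wound", sp))
  orig <- c("screw", "implant", "wound")
  got <- strsplit(out, " +")[[1]]
  expect_length(got, 3)
  for (i in 1:3) expect_equal(drop(adist(orig[i], got[i])), 1)

  # nonascii_rate = 1: every non-empty sentence gains a codepoint > 127
  na <- mk(misspell_rate = 0, whitespace_noise_rate = 0, nonascii_rate = 1)
  out2 <- notecodify:::with_seed(3, corrupt_text(txt, na))
  sents <- strsplit(out2, ".", fixed = TRUE)[[1]]
  sents <- sents[nzchar(trimws(sents))]
  has_nonascii <- vapply(
    sents,
    function(s) any(utf8ToInt(s) > 127), logical(1)
  )
  expect_true(all(has_nonascii))

  # whitespace injection never removes words
  ws <- mk(misspell_rate = 0, whitespace_noise_rate = 1, nonascii_rate = 0)
  out3 <- notecodify:::with_seed(4, corrupt_text(txt, ws))
  expect_identical(preprocess_text(out3), preprocess_text(txt))
})

test_that("signature overlap with the confuser is non-decreasing in ambiguity", {
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  overlaps <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(a) {
    specs <- make_code_specs(4, prevalence_range = c(0.2, 0.3), ambiguity = a)
    sm <- notecodify:::effective_signatures(specs)
    mean(c(jaccard(sm[[1]], sm[[2]]), jaccard(sm[[3]], sm[[4]])))
  })
  expect_true(all(diff(overlaps) >= 0))
  expect_equal(overlaps[1], 0) # ambiguity 0: disjoint
  expect_equal(overlaps[5], 1) # ambiguity 1: fully shared
})

test_that("zero-ambiguity fully-emitted corpora are nearest-centroid separable", {
  # a single shared template isolates the separability dial: boilerplate
  # cancels between the class centroids and only signatures remain
  specs <- make_code_specs(4,
    prevalence_range = c(0.2, 0.25), ambiguity = 0,
    signature_emission_prob = 1
  )
  cfg <- generator_config(100, specs,
    n_surgeons = 1, templates_per_surgeon = 1,
    misspell_rate = 0, whitespace_noise_rate = 0, nonascii_rate = 0, seed = 21
  )
  g <- generate_corpus(cfg)
  corp <- g$corpus
  m <- fit_tfidf(corp$tokens)
  fm <- transform_tfidf(m, corp$tokens, corp$note_id)
  for (code in corp$codes) {
    y <- corp$labels[, code]
    centroid_pos <- colMeans(fm$values[y == 1, , drop = FALSE])
    centroid_neg <- colMeans(fm$values[y == 0, , drop = FALSE])
    d_pos <- sqrt(colSums((t(fm$values) - centroid_pos)^2))
    d_neg <- sqrt(colSums((t(fm$values) - centroid_neg)^2))
    pred <- as.integer(d_pos < d_neg)
    expect_equal(pred, unname(y))
  }
})

test_that("configs that starve a code of positives are rejected", {
  specs <- make_code_specs(3, prevalence_range = c(0.002, 0.3))
  expect_error(generator_config(100, specs), "expected positive count")
  expect_error(
    generator_config(20, make_code_specs(3, prevalence_range = c(0.3, 0.5))),
    "10 x"
  )
})
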