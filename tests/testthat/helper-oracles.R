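# Independent brute-force oracles used to validate the fast implementations.

# AUROC by exhaustive pair counting (ties count one half)
oracle_auroc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# same-label neighbor ratio via the full distance matrix and explicit sort
oracle_ratio <- function(x, y, frac = 0.10) {
  n <- nrow(x)
  pos <- which(y == 1)
  M <- max(1, round(frac * length(pos)))
  dm <- as.matrix(dist(x))
  r <- sapply(pos, function(i) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(dm[i, others], others)]
    nb <- ord[seq_len(min(M, length(ord)))]
    mean(y[nb] == 1)
  })
  mean(r)
}

# normalized same-label radius via the full distance matrix
oracle_distance <- function(x, y, frac = 0.10) {
  pos <- which(y == 1)
  m <- max(1, round(frac * (length(pos) - 1)))
  dm <- as.matrix(dist(x))
  radii <- sapply(pos, function(i) {
    d <- sort(dm[i, setdiff(pos, i)])
    d[min(m, length(d))]
  })
  # per-note normalization by the corpus diameter, then the mean
  mean(radii / max(dm))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Ws <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  p_le <- mean(Ws <= W_obs + 1e-9)
  p_ge <- mean(Ws >= W_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# two-group one-way ANOVA F from raw sums of squares
oracle_anova_f <- function(v, y) {
  g1 <- v[y == 1]; g0 <- v[y == 0]
  n <- length(v)
  m <- mean(v)
  between <- length(g1) * (mean(g1) - m)^2 + length(g0) * (mean(g0) - m)^2
  within <- sum((g1 - mean(g1))^2) + sum((g0 - mean(g0))^2)
  if (within == 0) {
    if (between == 0) 0 else Inf
  } else {
    between / (within / (n - 2))
  }
}

# a tiny deterministic corpus with fully separable signatures
separable_corpus <- function(n = 120, n_codes = 4, seed = 11,
                             prevalence = 0.25, ambiguity = 0) {
  specs <- make_code_specs(n_codes,
    prevalence_range = c(prevalence * 0.8, prevalence),
    ambiguity = ambiguity, signature_emission_prob = 1
  )
  cfg <- generator_config(n, specs,
    misspell_rate = 0, whitespace_noise_rate = 0, nonascii_rate = 0,
    seed = seed
  )
  generate_corpus(cfg)
}
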