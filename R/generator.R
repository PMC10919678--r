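# Seeded synthetic operative-note corpora.
#
# Real operative notes are PHI and cannot ship with the package, so every
# downstream stage is exercised on generated corpora that reproduce the
# statistical structure such notes are known for: per-surgeon boilerplate
# templates, procedure-specific signature vocabulary, misspellings, whitespace
# runs and non-ASCII artifacts, multi-label code assignment with strongly
# imbalanced per-code prevalence, and one-sided label noise (missed codes).

.wordlist_cache <- new.env(parent = emptyenv())

wordlist <- function(which = c("filler", "signature")) {
  which <- match.arg(which)
  if (!is.null(.wordlist_cache[[which]])) return(.wordlist_cache[[which]])
  fn <- c(filler = "filler_vocabulary.txt", signature = "signature_terms.txt")[[which]]
  path <- system.file("extdata", fn, package = "notecodify")
  if (!nzchar(path)) path <- file.path("inst", "extdata", fn)
  words <- readLines(path, warn = FALSE)
  .wordlist_cache[[which]] <- words
  words
}

#' Specify one procedure code for the generator
#'
#' @param code_id Code label, e.g. `"29888"`.
#' @param prevalence Target positive fraction in (0, 1).
#' @param signature_terms Non-empty character vector of code-specific keywords
#'   emitted in positive notes.
#' @param signature_emission_prob Probability each signature term appears in a
#'   positive note's signature sentence.
#' @param ambiguity In `[0, 1]`: the fraction of signature terms shared with
#'   the code's designated confuser, and (at `ambiguity/2`) the per-note
#'   probability that the signature sentence is omitted entirely. 0 gives
#'   disjoint, always-present signatures; 1 gives signatures fully shared
#'   with the confuser and frequently absent.
#' @return A `code_spec` list.
#' @export
code_spec <- function(code_id, prevalence, signature_terms,
                      signature_emission_prob = 0.9, ambiguity = 0) {
  stopifnot(length(code_id) == 1, nzchar(code_id))
  if (!(is.numeric(prevalence) && prevalence > 0 && prevalence < 1)) {
    stop_bad("prevalence must be in (0,1) for code %s", code_id)
  }
  if (length(signature_terms) == 0) stop_bad("signature_terms empty for code %s", code_id)
  if (!is_prob(signature_emission_prob)) stop_bad("signature_emission_prob not in [0,1]")
  if (!is_prob(ambiguity)) stop_bad("ambiguity not in [0,1]")
  structure(
    list(
      code_id = as.character(code_id), prevalence = prevalence,
      signature_terms = as.character(signature_terms),
      signature_emission_prob = signature_emission_prob,
      ambiguity = ambiguity
    ),
    class = "code_spec"
  )
}

#' Build a default set of code specs
#'
#' Convenience constructor: code ids in the musculoskeletal range, prevalences
#' log-spaced across `prevalence_range` (most common first), and disjoint
#' signature-term blocks drawn from the shipped signature pool.
#'
#' @param n_codes Number of codes.
#' @param prevalence_range Length-2 numeric; prevalences are log-spaced from
#'   the upper to the lower bound. The default spans the roughly 10% to 0.2%
#'   positive-class prevalence envelope reported for the 100 most common
#'   musculoskeletal procedure codes in a large operative-note corpus, but
#'   desk-scale corpora usually narrow it so every code keeps enough
#'   positives for cross-validation.
#' @param terms_per_code Signature terms per code.
#' @param ambiguity Scalar or vector (recycled) of per-code ambiguities.
#' @param signature_emission_prob Scalar or vector, recycled likewise.
#' @return List of `code_spec`.
#' @export
make_code_specs <- function(n_codes, prevalence_range = c(0.002, 0.10),
                            terms_per_code = 6, ambiguity = 0,
                            signature_emission_prob = 0.9) {
  stopifnot(is_count(n_codes))
  pool <- wordlist("signature")
  if (n_codes * terms_per_code > length(pool)) {
    stop_bad("signature pool exhausted: need %d terms", n_codes * terms_per_code)
  }
  prev <- exp(seq(log(max(prevalence_range)), log(min(prevalence_range)),
    length.out = n_codes
  ))
  ambiguity <- rep_len(ambiguity, n_codes)
  emit <- rep_len(signature_emission_prob, n_codes)
  lapply(seq_len(n_codes), function(j) {
    terms <- pool[((j - 1) * terms_per_code + 1):(j * terms_per_code)]
    code_spec(sprintf("2%04d", 100 + j), prev[j], terms,
      signature_emission_prob = emit[j], ambiguity = ambiguity[j]
    )
  })
}

#' Generator configuration
#'
#' @param n_notes Number of notes (at least 10 per code).
#' @param codes List of [code_spec()] objects.
#' @param n_surgeons Number of surgeons, each with their own templates.
#' @param templates_per_surgeon Boilerplate templates per surgeon.
#' @param template_length Sentences per template.
#' @param misspell_rate Per-word probability of a single-character edit.
#' @param whitespace_noise_rate Per-sentence probability of an injected run of
#'   spaces/newlines.
#' @param nonascii_rate Per-sentence probability of an injected non-ASCII
#'   character.
#' @param label_flip_rate Per positive (note, code) probability that the
#'   recorded label is flipped to negative (a missed code).
#' @param seed Integer seed; fully determines the corpus.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_notes, codes, n_surgeons = 5,
                             templates_per_surgeon = 2, template_length = 8,
                             misspell_rate = 0.02, whitespace_noise_rate = 0.1,
                             nonascii_rate = 0.05, label_flip_rate = 0,
                             seed = 1L) {
  stopifnot(is_count(n_notes), is_count(n_surgeons),
    is_count(templates_per_surgeon), is_count(template_length)
  )
  if (!length(codes) || !all(vapply(codes, inherits, logical(1), "code_spec"))) {
    stop_bad("codes must be a non-empty list of code_spec objects")
  }
  ids <- vapply(codes, `[[`, character(1), "code_id")
  if (anyDuplicated(ids)) stop_bad("duplicate code_id in codes")
  for (r in c(misspell_rate, whitespace_noise_rate, nonascii_rate, label_flip_rate)) {
    if (!is_prob(r)) stop_bad("all noise rates must be probabilities in [0,1]")
  }
  if (n_notes < 10 * length(codes)) {
    stop_bad("n_notes must be at least 10 x number of codes")
  }
  exp_pos <- n_notes * vapply(codes, `[[`, numeric(1), "prevalence")
  if (any(exp_pos < 5)) {
    stop_bad(
      "expected positive count < 5 for code %s; downstream cross-validation undefined",
      ids[which(exp_pos < 5)[1]]
    )
  }
  structure(
    list(
      n_notes = as.integer(n_notes), codes = codes,
      n_surgeons = as.integer(n_surgeons),
      templates_per_surgeon = as.integer(templates_per_surgeon),
      template_length = as.integer(template_length),
      misspell_rate = misspell_rate,
      whitespace_noise_rate = whitespace_noise_rate,
      nonascii_rate = nonascii_rate, label_flip_rate = label_flip_rate,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Confuser pairing (1<->2, 3<->4, ...) and signature sharing. For a pair with
# ambiguities a1, a2, code i replaces its first round(a_i * L) terms with the
# partner's corresponding originals, so pairwise Jaccard overlap is
# non-decreasing in ambiguity. The odd code out keeps its own terms.
effective_signatures <- function(codes) {
  k <- length(codes)
  sigs <- lapply(codes, `[[`, "signature_terms")
  out <- sigs
  for (i in seq(1, k - 1, by = 2)) {
    if (i + 1 > k) break
    j <- i + 1
    li <- length(sigs[[i]]); lj <- length(sigs[[j]])
    # the shared block is the lower-indexed member's leading terms, so the
    # lower member's effective signature is unchanged; the partner replaces
    # its leading round(a * L) terms with that canonical block
    kj <- min(round(codes[[j]]$ambiguity * lj), li)
    if (kj > 0) out[[j]][seq_len(kj)] <- sigs[[i]][seq_len(kj)]
  }
  names(out) <- vapply(codes, `[[`, character(1), "code_id")
  out
}

confuser_of <- function(k) {
  conf <- rep(NA_integer_, k)
  for (i in seq(1, k - 1, by = 2)) {
    if (i + 1 <= k) {
      conf[i] <- i + 1L
      conf[i + 1] <- i
    }
  }
  conf
}

#' Apply character-level noise to note text
#'
#' Emulates the noise profile of hurriedly written, form-saved notes: per-word
#' single-character edits (substitute, drop, or duplicate one character — each
#' perturbed word ends at edit distance exactly 1 from the original), injected
#' runs of spaces/newlines, and injected non-ASCII characters, all at the
#' configured per-word / per-sentence rates. Uses the current RNG stream; with
#' all rates zero the text is returned unchanged.
#'
#' @param text A single string; sentences are the `.`-delimited segments.
#' @param config A `generator_config` (only the three noise rates are read).
#' @return The corrupted string.
#' @export
corrupt_text <- function(text, config) {
  stopifnot(length(text) == 1, nzchar(text))
  mr <- config$misspell_rate
  wr <- config$whitespace_noise_rate
  ar <- config$nonascii_rate
  if (mr == 0 && wr == 0 && ar == 0) return(text)
  sentences <- strsplit(text, ".", fixed = TRUE)[[1]]
  nonascii <- c("\u00a0", "\u00e9", "\u00b0", "\u2022", "\u00ae")
  out <- vapply(sentences, function(s) {
    if (!nzchar(trimws(s))) return(s)
    words <- strsplit(trimws(s), " +")[[1]]
    if (mr > 0) {
      hit <- stats::runif(length(words)) < mr
      words[hit] <- vapply(words[hit], misspell_word, character(1))
    }
    s2 <- paste(words, collapse = " ")
    if (wr > 0 && stats::runif(1) < wr) {
      pos <- sample(length(words), 1)
      filler <- paste(rep(sample(c(" ", "\n"), 1), sample(2:6, 1)), collapse = "")
      words2 <- words
      words2[pos] <- paste0(words2[pos], filler)
      s2 <- paste(words2, collapse = " ")
    }
    if (ar > 0 && stats::runif(1) < ar) {
      s2 <- paste0(s2, sample(nonascii, 1))
    }
    s2
  }, character(1), USE.NAMES = FALSE)
  paste(out, collapse = ". ")
}

# one random single-character edit, always at plain edit distance 1
misspell_word <- function(w) {
  chars <- strsplit(w, "")[[1]]
  n <- length(chars)
  op <- if (n == 1) sample(c("sub", "dup"), 1) else sample(c("sub", "drop", "dup"), 1)
  i <- sample(n, 1)
  letters_pool <- setdiff(letters, tolower(chars[i]))
  switch(op,
    sub = paste0(c(chars[seq_len(i - 1)], sample(letters_pool, 1), chars[-seq_len(i)]),
      collapse = ""
    ),
    drop = paste0(chars[-i], collapse = ""),
    dup = paste0(c(chars[seq_len(i)], chars[i], chars[-seq_len(i)]), collapse = "")
  )
}

#' Flip recorded positive labels to negative at a given rate
#'
#' Models the dominant real-world labelling error for procedure codes: codes
#' that were performed but never recorded. Each positive entry of `labels` is
#' independently inverted with probability `rate`; negatives are never
#' touched. Uses the current RNG stream.
#'
#' @param labels Binary note x code matrix with dimnames.
#' @param rate Flip probability in `[0, 1]`.
#' @return List with `labels` (after flips) and `flips`, a data.frame of
#'   `note_id`, `code_id` pairs recording every inversion.
#' @export
inject_label_noise <- function(labels, rate) {
  if (!is_prob(rate)) stop_bad("rate must be in [0,1]")
  pos <- which(labels == 1L)
  flip <- if (rate == 0 || length(pos) == 0) {
    integer(0)
  } else {
    pos[stats::runif(length(pos)) < rate]
  }
  out <- labels
  out[flip] <- 0L
  rc <- arrayInd(flip, dim(labels))
  flips <- data.frame(
    note_id = rownames(labels)[rc[, 1]],
    code_id = colnames(labels)[rc[, 2]],
    stringsAsFactors = FALSE
  )
  list(labels = out, flips = flips)
}

#' Generate a coded corpus with known ground truth
#'
#' Each note is one surgeon template (boilerplate sentences over a shared
#' filler vocabulary) followed by a signature sentence per assigned code, then
#' corrupted by [corrupt_text()]. Clean labels are per-code Bernoulli draws at
#' the configured prevalences, repaired so every note carries 1–3 codes;
#' recorded labels are the clean labels with one-sided flips applied at
#' `label_flip_rate`. The seed fully determines the output, and each code's
#' label draws come from a derived sub-stream, so extending the code list
#' leaves earlier codes' draws untouched.
#'
#' @param config A [generator_config()].
#' @return List with `corpus` (a [coded_corpus()] built from the recorded,
#'   i.e. post-flip, labels) and `truth`, containing `signature_map` (the
#'   effective per-code signature terms after confuser sharing),
#'   `template_assignment` (note_id, surgeon, template), `clean_labels`,
#'   `flips`, and `confuser` (per-code partner id or NA).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_notes
  codes <- config$codes
  k <- length(codes)
  ids <- vapply(codes, `[[`, character(1), "code_id")
  note_ids <- sprintf("note%05d", seq_len(n))
  prev <- vapply(codes, `[[`, numeric(1), "prevalence")

  # --- clean labels: one sub-stream per code, then a repair stream ----------
  labels <- matrix(0L, n, k, dimnames = list(note_ids, ids))
  for (j in seq_len(k)) {
    with_seed(derive_seed(config$seed, j), {
      labels[, j] <- stats::rbinom(n, 1L, prev[j])
    })
  }
  labels <- with_seed(derive_seed(config$seed, 999983), {
    repair_labels(labels, prev)
  })

  # --- recorded labels: one-sided flips ------------------------------------
  noised <- with_seed(derive_seed(config$seed, 424243), {
    inject_label_noise(labels, config$label_flip_rate)
  })

  # --- templates ------------------------------------------------------------
  filler <- wordlist("filler")
  templates <- with_seed(derive_seed(config$seed, 101), {
    lapply(seq_len(config$n_surgeons), function(s) {
      lapply(seq_len(config$templates_per_surgeon), function(t) {
        vapply(seq_len(config$template_length), function(i) {
          paste(sample(filler, sample(6:12, 1), replace = TRUE), collapse = " ")
        }, character(1))
      })
    })
  })

  sig_map <- effective_signatures(codes)
  emit <- vapply(codes, `[[`, numeric(1), "signature_emission_prob")
  ambig <- vapply(codes, `[[`, numeric(1), "ambiguity")

  # --- note text: per-note derived stream -----------------------------------
  texts <- character(n)
  surgeon <- integer(n)
  template_idx <- integer(n)
  for (i in seq_len(n)) {
    with_seed(derive_seed(config$seed, 100000 + i), {
      s <- sample(config$n_surgeons, 1)
      t <- sample(config$templates_per_surgeon, 1)
      surgeon[i] <- s
      template_idx[i] <- t
      sents <- templates[[s]][[t]]
      for (j in which(labels[i, ] == 1L)) {
        if (stats::runif(1) < ambig[j] / 2) next # signature omitted
        terms <- sig_map[[j]]
        keep <- stats::runif(length(terms)) < emit[j]
        if (!any(keep)) next
        sig_sent <- paste(
          c(terms[keep], sample(filler, 2, replace = TRUE)),
          collapse = " "
        )
        sents <- c(sents, sig_sent)
      }
      txt <- paste0(paste(sents, collapse = ". "), ".")
      texts[i] <- corrupt_text(txt, config)
    })
  }

  corpus <- coded_corpus(note_ids, texts, noised$labels)
  truth <- list(
    signature_map = sig_map,
    template_assignment = data.frame(
      note_id = note_ids, surgeon = surgeon, template = template_idx,
      stringsAsFactors = FALSE
    ),
    clean_labels = labels,
    flips = noised$flips,
    confuser = stats::setNames(ids[confuser_of(k)], ids)
  )
  list(corpus = corpus, truth = truth)
}

# Enforce 1-3 codes per note while preserving each code's marginal draw as
# far as possible: empty notes gain one code sampled proportional to
# prevalence; notes with >3 codes keep 3 of their positives at random.
repair_labels <- function(labels, prev) {
  n_codes <- ncol(labels)
  rs <- rowSums(labels)
  for (i in which(rs == 0)) {
    labels[i, sample(n_codes, 1, prob = prev)] <- 1L
  }
  for (i in which(rs > 3)) {
    pos <- which(labels[i, ] == 1L)
    drop <- sample(pos, length(pos) - 3L)
    labels[i, drop] <- 0L
  }
  labels
}

#' Write generator ground truth as JSON
#'
#' Sidecar for [generate_corpus()]: signature map, template assignment, flip
#' list and confuser pairing, readable with [jsonlite::fromJSON()].
#'
#' @param truth The `truth` element returned by [generate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- list(
    signature_map = truth$signature_map,
    template_assignment = truth$template_assignment,
    flips = truth$flips,
    confuser = as.list(truth$confuser)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
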