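# Orchestrated experiments: method benchmark, complexity-stratified
# data-reduction study, and the label-noise quality audit.

#' Define a feature-extraction family for the benchmark
#'
#' A family bundles a name with a featurizer `function(corpus, train_idx)`
#' returning a [feature_matrix()] over ALL notes (supervised pieces — IDF and
#' keyword selection — are fit on `train_idx` only) and a flag saying whether
#' the per-code keyword count K is tuned.
#'
#' @param name Family label used in comparison tables.
#' @param featurize `function(corpus, train_idx) -> feature_matrix`.
#' @param tunes_k Whether hyperparameter search should tune ANOVA-F top-K
#'   selection inside its CV folds.
#' @param fixed_k Optional fixed keyword count applied per code (fit on the
#'   training split), e.g. 100 or 500.
#' @return A `feature_family`.
#' @export
feature_family <- function(name, featurize, tunes_k = FALSE, fixed_k = NULL) {
  stopifnot(is.character(name), is.function(featurize))
  structure(
    list(name = name, featurize = featurize, tunes_k = tunes_k, fixed_k = fixed_k),
    class = "feature_family"
  )
}

#' TF-IDF feature families
#'
#' The four keyword-selection settings: all features, top 100, top 500, and
#' tuned K (log-uniform search per code).
#'
#' @param setting One of `"all"`, `"top100"`, `"top500"`, `"topK"`.
#' @return A [feature_family()].
#' @export
tfidf_family <- function(setting = c("all", "top100", "top500", "topK")) {
  setting <- match.arg(setting)
  featurize <- function(corpus, train_idx) {
    model <- fit_tfidf(corpus$tokens[train_idx])
    fm <- transform_tfidf(model, corpus$tokens, corpus$note_id)
    fm$provenance$setting <- setting
    fm
  }
  feature_family(
    paste0("tfidf_", setting), featurize,
    tunes_k = setting == "topK",
    fixed_k = switch(setting, top100 = 100L, top500 = 500L, NULL)
  )
}

#' Paragraph-vector feature family
#'
#' @param config A [doc2vec_config()].
#' @param seed Seed for the embedding training (unsupervised, fit on the
#'   full corpus).
#' @param ... Passed to [doc2vec_features()].
#' @return A [feature_family()].
#' @export
doc2vec_family <- function(config = doc2vec_config(), seed = 1L, ...) {
  feature_family(
    sprintf("doc2vec_D%d_W%d_%s", config$D, config$W, config$mode),
    function(corpus, train_idx) doc2vec_features(corpus, config, seed = seed, ...)
  )
}

#' Chunked token-embedding feature family
#'
#' @param mode Aggregation mode for [embed_corpus()].
#' @param backend An embedding backend (default: the seeded hashed-random
#'   backend).
#' @return A [feature_family()].
#' @export
embedding_family <- function(mode = "A_W", backend = hash_embedding_backend()) {
  feature_family(
    paste0("embed_", paste(mode, collapse = "+")),
    function(corpus, train_idx) embed_corpus(backend, corpus, mode)
  )
}

# per-(family, code) pipeline: split -> featurize -> tune -> final fit
run_code_pipeline <- function(corpus, family, code_id, seed,
                              space = search_space(), test_fraction = 0.2) {
  y <- corpus$labels[, code_id]
  split <- stratified_split(y, test_fraction,
    seed = derive_seed(seed, string_hash(code_id)), code_id = code_id
  )
  fm <- family$featurize(corpus, split$train)
  x <- fm$values
  sp <- space
  if (isTRUE(family$tunes_k)) {
    if (is.null(sp$K_range)) sp$K_range <- c(10L, ncol(x))
    sp$K_range <- pmin(sp$K_range, ncol(x))
  } else {
    sp$K_range <- NULL
  }
  if (!is.null(family$fixed_k)) {
    fv <- anova_f(x[split$train, , drop = FALSE], y[split$train])
    cfg <- selection_config("topK", K = min(family$fixed_k, ncol(x)))
    fm <- select_features(fm, fv, cfg)
    x <- fm$values
  }
  tuned <- tune_svm(x[split$train, , drop = FALSE], y[split$train], sp,
    seed = derive_seed(seed, string_hash(paste0(family$name, code_id)))
  )
  res <- train_and_evaluate(x, y, split, tuned$params,
    code_id = code_id, cv_auroc = tuned$cv_auroc
  )
  res$family <- family$name
  res$split <- split
  res$features <- fm
  res
}

#' Benchmark feature families across all codes
#'
#' For every (family, code) pair: stratified split, featurization, seeded
#' hyperparameter search, final training and test-set evaluation; assembles
#' the codes x families AUROC table and, with two or more families, the
#' rank-based comparison. Per-code failures are recorded as NA with a
#' warning rather than aborting the run.
#'
#' @param corpus A [coded_corpus()].
#' @param families List of [feature_family()] objects (>= 1).
#' @param seed Integer seed; fixes every split, fold and search draw.
#' @param space A [search_space()].
#' @param codes Codes to include (default: all).
#' @param test_fraction Held-out fraction per code.
#' @return A `benchmark_result`: `auroc_table` (codes x families),
#'   `cv_auroc_table`, `results` (nested per family), and `comparison`
#'   (a [method_comparison()], or NULL for a single family).
#' @export
run_benchmark <- function(corpus, families, seed = 1L, space = search_space(),
                          codes = NULL, test_fraction = 0.2) {
  stopifnot(inherits(corpus, "coded_corpus"), length(families) >= 1)
  codes <- codes %||% corpus$codes
  fam_names <- vapply(families, `[[`, character(1), "name")
  auroc_tab <- matrix(NA_real_, length(codes), length(families),
    dimnames = list(codes, fam_names)
  )
  cv_tab <- auroc_tab
  results <- stats::setNames(vector("list", length(families)), fam_names)
  for (f in seq_along(families)) {
    fam <- families[[f]]
    for (code in codes) {
      res <- tryCatch(
        run_code_pipeline(corpus, fam, code, seed, space, test_fraction),
        error = function(e) {
          warning(sprintf(
            "benchmark cell (%s, %s) failed: %s",
            fam$name, code, conditionMessage(e)
          ), call. = FALSE)
          NULL
        }
      )
      if (!is.null(res)) {
        auroc_tab[code, fam$name] <- res$metrics$auroc
        cv_tab[code, fam$name] <- res$cv_auroc
        res$features <- NULL # drop bulky feature matrices from the record
        results[[fam$name]][[code]] <- res
      }
    }
  }
  comparison <- NULL
  if (length(families) >= 2) {
    complete <- stats::complete.cases(auroc_tab)
    if (sum(complete) >= 2) {
      comparison <- method_comparison(auroc_tab[complete, , drop = FALSE])
    }
  }
  structure(
    list(
      auroc_table = auroc_tab, cv_auroc_table = cv_tab,
      results = results, comparison = comparison, seed = seed
    ),
    class = "benchmark_result"
  )
}

#' Data-reduction study
#'
#' For each code, removes `round(f * P_train)` randomly chosen positive
#' notes from the training pool at each reduction fraction `f` (the test
#' split is untouched, so AUROC stays comparable across fractions), refits
#' at the hyperparameters tuned on the full training pool, and records test
#' AUROC. Complexity strata can be attached via `profile`.
#'
#' @param corpus A [coded_corpus()].
#' @param family A [feature_family()].
#' @param fractions Reduction fractions in `[0, 0.9]` (default 0, 0.1, ...,
#'   0.9).
#' @param seed Integer seed.
#' @param space A [search_space()].
#' @param codes Codes to run (default: all).
#' @param profile Optional [complexity_profile()] data.frame supplying
#'   strata.
#' @param test_fraction Held-out fraction.
#' @return A data.frame: `code_id`, `stratum`, `fraction`, `auroc`,
#'   `n_train_pos` (NA AUROC where reduction left too few positives).
#' @export
run_reduction_study <- function(corpus, family, fractions = seq(0, 0.9, 0.1),
                                seed = 1L, space = search_space(), codes = NULL,
                                profile = NULL, test_fraction = 0.2) {
  stopifnot(all(fractions >= 0 & fractions <= 0.9))
  codes <- codes %||% corpus$codes
  rows <- list()
  for (code in codes) {
    base <- run_code_pipeline(corpus, family, code, seed, space, test_fraction)
    y <- corpus$labels[, code]
    x <- base$features$values
    split <- base$split
    train_pos <- intersect(split$train, which(y == 1L))
    stratum <- if (!is.null(profile)) {
      profile$stratum[match(code, profile$code_id)]
    } else {
      NA_character_
    }
    for (f in fractions) {
      if (f == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          code_id = code, stratum = stratum, fraction = 0,
          auroc = base$metrics$auroc, n_train_pos = length(train_pos),
          stringsAsFactors = FALSE
        )
        next
      }
      drop_n <- round(f * length(train_pos))
      kept_train <- with_seed(
        derive_seed(seed, string_hash(paste(code, f))),
        setdiff(split$train, sample(train_pos, drop_n))
      )
      n_pos_left <- sum(y[kept_train] == 1L)
      auc <- if (n_pos_left < space$folds + 1) {
        NA_real_
      } else {
        sub_split <- list(train = kept_train, test = split$test)
        tryCatch(
          train_and_evaluate(x, y, sub_split, base$params, code_id = code)$metrics$auroc,
          error = function(e) NA_real_
        )
      }
      rows[[length(rows) + 1]] <- data.frame(
        code_id = code, stratum = stratum, fraction = f, auroc = auc,
        n_train_pos = n_pos_left, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Label-noise quality audit
#'
#' Every note receives an out-of-fold prediction (stratified k-fold; each
#' fold is predicted by a model trained on the other folds at
#' hyperparameters tuned once per code), and notes whose prediction
#' disagrees with the recorded label are flagged. When generator ground
#' truth is supplied, flag precision (fraction of flags that are injected
#' flips) and recall (fraction of injected flips flagged) are computed.
#'
#' @param corpus A [coded_corpus()] (recorded, possibly noisy labels).
#' @param family A [feature_family()].
#' @param folds Cross-validation folds (>= 2, default 5).
#' @param seed Integer seed.
#' @param space A [search_space()] for the per-code tuning.
#' @param truth Optional `truth` from [generate_corpus()] (its `flips`).
#' @param codes Codes to audit (default: all).
#' @return A data.frame per code: `code_id`, `n_flagged`,
#'   `flag_precision`, `flag_recall` (NA without truth), plus attribute
#'   `flagged`, a named list of flagged note ids per code.
#' @export
run_quality_audit <- function(corpus, family, folds = 5, seed = 1L,
                              space = search_space(), truth = NULL,
                              codes = NULL) {
  stopifnot(is_count(folds), folds >= 2)
  codes <- codes %||% corpus$codes
  n <- length(corpus$note_id)
  all_idx <- seq_len(n)
  flagged_list <- stats::setNames(vector("list", length(codes)), codes)
  rows <- list()
  for (code in codes) {
    y <- corpus$labels[, code]
    fm <- family$featurize(corpus, all_idx)
    x <- fm$values
    sp <- space
    if (isTRUE(family$tunes_k)) {
      if (is.null(sp$K_range)) sp$K_range <- c(10L, ncol(x))
      sp$K_range <- pmin(sp$K_range, ncol(x))
    } else {
      sp$K_range <- NULL
    }
    if (!is.null(family$fixed_k)) {
      fv <- anova_f(x, y)
      fm <- select_features(fm, fv, selection_config("topK", K = min(family$fixed_k, ncol(x))))
      x <- fm$values
    }
    tuned <- tune_svm(x, y, sp, seed = derive_seed(seed, string_hash(paste0("audit", code))))
    assign <- stratified_folds(y, folds, derive_seed(seed, string_hash(paste0("folds", code))))
    pred <- integer(n)
    for (f in seq_len(folds)) {
      tr <- which(assign != f); te <- which(assign == f)
      xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
      if (!is.null(tuned$params$K)) {
        fv <- anova_f(xtr, y[tr])
        ord <- order(-fv, colnames(x))
        keep <- sort(ord[seq_len(min(tuned$params$K, ncol(x)))])
        xtr <- xtr[, keep, drop = FALSE]; xte <- xte[, keep, drop = FALSE]
      }
      scorer <- fit_rbf_svm(xtr, y[tr], tuned$params$C, tuned$params$gamma, code)
      pred[te] <- scorer(xte)$label
    }
    flagged <- corpus$note_id[pred != y]
    flagged_list[[code]] <- flagged
    if (!is.null(truth)) {
      fl <- truth$flips
      true_flips <- fl$note_id[fl$code_id == code]
      prec <- if (length(flagged)) mean(flagged %in% true_flips) else NA_real_
      rec <- if (length(true_flips)) mean(true_flips %in% flagged) else NA_real_
    } else {
      prec <- NA_real_; rec <- NA_real_
    }
    rows[[length(rows) + 1]] <- data.frame(
      code_id = code, n_flagged = length(flagged),
      flag_precision = prec, flag_recall = rec, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "flagged") <- flagged_list
  out
}
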