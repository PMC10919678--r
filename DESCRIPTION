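Package: notecodify
Title: Benchmarking Text Representations for Procedure-Code Assignment from Operative Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying automated assignment of procedure billing codes
    (CPT) to free-text operative notes. Provides a seeded synthetic-corpus
    generator that emulates the statistical structure of real operative notes
    (per-surgeon boilerplate templates, misspellings, whitespace and non-ASCII
    noise, multi-label code assignment, label noise), three feature-extraction
    families (TF-IDF with ANOVA F-value keyword selection, paragraph vectors,
    and chunked token-embedding aggregation), per-code RBF-kernel support
    vector machine classification with stratified splits and seeded
    hyperparameter search, rank-based method comparison (Friedman test,
    pairwise exact Wilcoxon signed-rank tests with Holm adjustment, and
    critical-difference cliques), a nearest-neighbour class-overlap complexity
    score for classification tasks, and orchestrated experiments: a method
    benchmark, a complexity-stratified data-reduction study, and a label-noise
    quality audit based on out-of-fold prediction disagreement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
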