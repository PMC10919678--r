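---
title: "Methods: benchmarking text representations for procedure-code assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking text representations for procedure-code assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Operative notes are free-text documents describing surgical procedures; each
carries one or more CPT (Current Procedural Terminology) billing codes.
Assigning those codes manually is slow and error-prone, and corpora of coded
notes are a natural benchmark for clinical NLP: the task is well defined
(per-code binary classification), strongly imbalanced (per-code prevalence
from roughly 10% down to fractions of a percent), and the text is noisy in a
characteristic way — per-surgeon boilerplate templates, misspellings,
acronyms, runs of whitespace, and non-ASCII artifacts from form-based
editors.

`notecodify` implements a complete, seeded pipeline for studying this task:
a synthetic corpus generator with known ground truth, three
feature-extraction families, per-code RBF-SVM classification with
cross-validated hyperparameter search, rank-based method comparison, a
nearest-neighbour complexity measure for individual codes, and three
orchestrated experiments (benchmark, data-reduction study, label-noise
audit). Real coded note corpora are protected health information and cannot
ship with a package; every stage is therefore developed and tested against
generated corpora whose statistical structure mirrors what is reported for
real operative notes.

## The synthetic corpus generator

Each note is built as: a boilerplate template (one of
`templates_per_surgeon` per surgeon, sentences drawn once from a shipped
~500-token filler vocabulary) followed by one signature sentence per
assigned code, then passed through a character-level corruption step. The
generator's dials:

* **Prevalence.** Clean labels are per-code Bernoulli draws; each code's
  draws come from a sub-stream derived from the corpus seed, so adding a
  code never perturbs earlier codes' labels. A repair pass then enforces
  1–3 codes per note (notes with several CPTs are the norm; label-free
  notes are not generated): an empty note gains one code sampled
  proportional to prevalence, a note with more than three keeps three at
  random. With few codes and low total prevalence mass this conditioning
  inflates observed prevalence above the nominal rate (by roughly the
  probability of an empty draw, shared proportionally); with code sets
  whose prevalences sum well above one — the realistic multi-label regime —
  the distortion is well inside binomial noise, which is the regime the
  package's prevalence-recovery tests use.
* **Ambiguity.** Codes are paired with a *confuser* (1↔2, 3↔4, ...). At
  ambiguity `a`, a fraction `a` of a code's signature terms is replaced by
  the confuser's, and the whole signature sentence is omitted from a
  positive note with probability `a/2`. At `a = 0` signatures are disjoint
  and (at emission probability 1) always present — the corpus is exactly
  separable; at `a = 1` the pair's signatures are identical and half the
  positives carry no signature at all, so the code is learnable only
  statistically and only with enough positive examples. The omission rate
  is capped at 1/2 by design: a dial that removed all signal at `a = 1`
  would make the hardest stratum indistinguishable from random labels, and
  no data-size effect could exist there.
* **Noise.** Per-word single-character edits (substitute, drop, duplicate —
  each perturbed word ends at plain edit distance exactly 1; adjacent-
  character swaps are excluded because they are distance 2 under the
  ordinary Levenshtein metric the tests use), per-sentence whitespace runs,
  and per-sentence non-ASCII characters. Quantitative rates of such
  noise in real notes are not published; the defaults (0.02 / 0.10 / 0.05)
  are deliberate, fixed dials chosen to be visible in the vocabulary
  (misspellings inflate it markedly) without overwhelming the signal.
* **Label noise.** Recorded labels are the clean labels with each positive
  flipped to negative independently at `label_flip_rate`. Flips are
  one-sided because the dominant real-world error is a performed procedure
  that was never coded, and one-sided flips keep the audit's ground truth
  unambiguous.

What passing tests on these corpora do *not* show: linguistic realism
(grammar, negation, section structure), coder-specific biases, or the tail
behaviour of a 44,000-note hospital corpus. They do show that every
algorithmic component behaves as specified on data with the right
first-order statistics (templates, imbalance, noise, label errors).

## Feature families

* **TF-IDF.** Smoothed convention `idf(t) = ln((1+N)/(1+df(t))) + 1` on raw
  counts with L2 row normalization — the dominant variant, so intuition
  about extracted "keywords" transfers. Vocabulary and document frequencies
  are fit on training notes only. Keyword selection ranks features by the
  two-group ANOVA F-value against the target code; settings are all
  features, top 100, top 500, or top K with K tuned per code. Infinite
  F-values (zero within-group variance) rank above all finite ones and
  ties break by feature name, so the ordering is total and reproducible.
  Selection is refit inside every cross-validation training fold, so tuned
  K never sees validation labels.
* **Paragraph vectors.** A compact PV-DM / PV-DBOW trainer with negative
  sampling, single-threaded and seeded so reruns are bit-identical. It is
  written for the package's corpus sizes (hundreds of notes); the
  configuration grid (dimension `D`, window `W`, DM vs DBOW) is the tested
  surface, not trainer throughput. Embeddings are fit unsupervised on the
  full corpus (transductive, the standard paragraph-vector practice).
* **Chunked token embeddings.** Long notes are split into contiguous chunks
  of at most `max_chunk` tokens; a backend embeds each chunk into per-token
  vectors plus a summary ([CLS]-role) vector; pooling is mean/max over all
  tokens (`A_W`, `M_W`) or over chunk summaries (`A_CLS`, `M_CLS`), or a
  concatenation of two modes. `A_W` is token-weighted (a mean over all
  tokens regardless of chunking), which makes it invariant to the chunk
  boundaries. The default backend maps each token to a fixed pseudo-random
  Gaussian vector derived from a hash of the token string — deterministic,
  dependency-free, and sufficient to exercise every aggregation path; a
  clinically pre-trained transformer can be plugged in behind the same
  contract. End-to-end transformer fine-tuning is out of scope by design:
  at fractions-of-a-percent prevalence it is known not to converge
  reliably, and the package's interest is the representations.

## Classification and tuning

One binary RBF-SVM per code, with class weights inversely proportional to
class frequency (without this, sub-percent-prevalence codes collapse to the
majority class). The operating point for sensitivity/specificity is the
sign of the SVM margin. 20% of notes are held out with stratification; the
remaining 80% drive hyperparameter search scored by mean stratified k-fold
cross-validated AUROC.

The search itself is a seeded sequential scheme: the first half of the
budget samples `C`, `gamma` (and `K`, when tuned) log-uniformly from their
ranges; the second half samples lognormal perturbations around the
incumbent best, clipped to the ranges. This is a deliberately simple,
fully reproducible exploration/exploitation schedule standing where a
model-based Bayesian optimizer would otherwise sit; the contract is only
"best evaluated point under a fixed seed". Defaults: `C` in [1e-2, 1e3],
`gamma` in [1e-4, 1e1], `K` in [10, vocabulary], all log-uniform — the
log-uniform shape for `K` biases toward smaller keyword sets, guarding
against overfitting. Default budget is 50 evaluations with 5 folds;
the experiment drivers in this vignette and the tests run budgets of 3–6
with 3 folds, which is where the corpus sizes used here (250–1000 notes,
3–10 codes) already saturate.

AUROC is computed in Mann-Whitney form from midranks (ties count one half),
so it agrees exactly with exhaustive pair counting and is invariant under
monotone transforms of the decision scores.

## Rank-based method comparison

AUROC tables (codes as tasks, methods as columns) are compared with:
within-task ranks (ties averaged; rank 1 = best), the tie-corrected
Friedman chi-square with `k - 1` degrees of freedom (two methods delegate
to the signed-rank test), all pairwise two-sided Wilcoxon signed-rank tests
(zeros dropped; exact null by dynamic programming over doubled ranks up to
n = 25, normal approximation with tie correction beyond), and Holm
step-down adjustment. Critical-difference cliques are the maximal
rank-contiguous groups of two or more methods whose internal adjusted
p-values all exceed alpha; when every pair differs significantly each
method stands alone. The statistical content is the tested surface; the
diagram drawing (`plot_cd_diagram`) is a convenience.

## The complexity measure

For one code in a given feature space, with `P` positive notes:

* **ratio** — for each positive note, the fraction of its
  `M = max(1, round(0.10 * P))` nearest notes (Euclidean, self excluded)
  that share the label, averaged over positives;
* **distance** — for each positive note, the distance to its
  `m = max(1, round(0.10 * (P - 1)))`-th nearest *same-label* neighbour,
  normalized by the corpus diameter (the largest pairwise distance over
  all notes, read literally as the whole dataset), averaged over
  positives;
* **score** — `ln(distance / ratio)`, natural log (the base only shifts
  the scale, and the strata bounds are configurable). Lower is simpler.

Choices made where the definition was open: `M` uses `max(1, round(.))` so
codes with around ten positives remain defined; the `m`-th same-label
neighbour counts the *other* positives (`P - 1`, self excluded everywhere);
a ratio or radius of exactly 0 (duplicated notes) is clamped to
`1/(2n)` before the log so degenerate geometries stay finite and ordered;
the measure is computed on the full corpus, not a training split, because
it describes the dataset rather than a fitted model. Strata default to
low < 1 ≤ medium ≤ 2 < high; the published boundary between "low" and
"medium" is stated inconsistently at both 1 and 2 in the literature this
follows, so the bounds are explicit configuration rather than constants.
The measure is invariant under rotation and uniform scaling of the feature
space, and both components are validated exactly against a quadratic-time
brute-force oracle.

## Experiments

* **Benchmark** (`run_benchmark`): per (family, code) — stratified split,
  featurization, tuning, final fit, test metrics; failures degrade to NA
  cells with warnings rather than aborting a hundred-code run.
* **Reduction study** (`run_reduction_study`): per code, remove
  `round(f * P_train)` random training positives at each fraction `f` (test
  set untouched, so AUROC stays comparable), refit at the hyperparameters
  tuned at `f = 0`, and record test AUROC. Re-tuning every cell would
  multiply cost roughly tenfold without changing the measured effect — the
  question is how performance responds to data volume, not whether the
  optimizer can track it.
* **Quality audit** (`run_quality_audit`): hyperparameters tuned once per
  code, then stratified k-fold refits give every note an out-of-fold
  prediction; disagreements with the recorded label are flagged, and with
  generator truth available the flags are scored as precision/recall
  against the injected flips. On a low-ambiguity corpus with 2% one-sided
  flips, flagged notes are overwhelmingly genuine label errors — the
  phenomenon that makes classifier disagreement useful for coding quality
  control.

## Numerical and degenerate-input conventions

Scores tie-break deterministically everywhere (feature name for F-values,
note index for neighbour distances, code id for prevalence ranks). All
randomness flows from explicit integer seeds through derived sub-streams;
every public operation restores the caller's RNG state. Degenerate inputs
are either errors with the offending code named (single-class labels, zero
corpus diameter, starved splits) or documented clamps (complexity zeros),
never silent NaNs.

## Problem sizes

The shipped tests and the acceptance script run, by choice, at desk scale:
corpora of 250–1000 notes, 2–10 codes, prevalences 6–30%, search budgets
3–6 over 3 folds. These sizes are where the generated task is already
non-trivial (noisy vocabulary of ~2000 terms, confusable code pairs,
sub-10-positive training pools after reduction) while each experiment
completes in minutes on one CPU. Scaling the same calls to
hundred-code corpora is a matter of budget, not code path.

## Known limitations

The generator's omission/sharing ambiguity dial is one specific model of
confusability; real codes are confusable for many reasons (shared anatomy,
nested procedures) that a term-sharing dial only sketches. The paragraph-
vector trainer is a faithful but small implementation — for corpora of tens
of thousands of notes a compiled trainer would be appropriate. The audit
assumes one-sided label noise; two-sided noise would need a different
ground-truth bookkeeping. And all reported numbers are properties of
generated corpora: they demonstrate correctness and qualitative behaviour,
not clinical performance.
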