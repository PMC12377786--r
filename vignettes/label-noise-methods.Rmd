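---
title: "Outcome-label noise in EHR-based risk prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outcome-label noise in EHR-based risk prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Risk prediction models built from electronic health records (EHRs) inherit
the quality of the outcome labels recorded in them. For gestational diabetes
mellitus (GDM), the diagnosis recorded in a hospital EHR can disagree
substantially with the clinician-maintained, laboratory-confirmed registry
of the same hospital: a meaningful fraction of true cases never receive an
EHR diagnosis code (false negatives) and a smaller fraction of non-cases do
(false positives). `gdmnoise` packages the machinery needed to study what
such discordance does to a prediction model, in three steps:

1. **Validation** — quantify agreement between a noisy label source and a
   reference: confusion composition, sensitivity-style rates, accuracy,
   precision, recall, F1, Cohen's kappa, with per-year stratification.
2. **Label-source experiment** — train the same logistic model under the
   noisy labels and under validated (agreement-subset) labels, and evaluate
   under each, isolating train-side from test-side noise.
3. **Noise sweeps** — inject class-conditional noise at levels 0–90% into
   the training labels (refitting per cell) and separately into the test
   labels (rescoring a fixed model), mapping ROC AUC and average precision
   over the false-negative × false-positive grid.

Because hospital EHR extracts cannot be shared, the package ships a
synthetic-cohort generator that reproduces the statistical structure the
analysis depends on, so every step is runnable and testable end to end.

## The synthetic cohort

`generate_cohort()` draws one record per pregnancy. Its defaults emulate a
five-year antenatal booking cohort of a large Irish maternity hospital:

* **Numeric features** (truncated normal): age 32 ± 5 y (≥ 18), BMI
  26.2 ± 5.3 kg/m² (14–60), systolic BP 111 ± 11 mm Hg, diastolic BP
  67 ± 8 mm Hg, parity 0.9 ± 1.1 rounded to a non-negative integer.
  Truncation uses exact inverse-CDF sampling, so means converge to the
  specification up to the (small) truncation shift.
* **Categorical features**: ethnic origin (8 levels, 87.8% Caucasian),
  occupation skill level (5 levels), family history of diabetes (23.3%),
  previous GDM (3.9%), other endocrine problems (21.4%).
* **Filler features**: 60 standard-normal noise columns, so the one-hot
  design matrix has 79 columns (5 numeric + 7 + 4 contrasts + 3 binaries +
  60 fillers) — the width a realistic booking-visit feature set reaches
  after encoding.
* **Outcome**: a latent logistic model. Numeric features enter standardized
  by their *specification* mean/SD (so coefficients are per-SD log-odds);
  categorical contrasts are indicators named `"feature:level"`. The
  intercept is calibrated on the generated sample by monotone bisection
  (`calibrate_intercept()`, tolerance 1e-6 on the achieved mean risk,
  hard cap of 200 steps) so the expected prevalence equals
  `target_prevalence`, 10.5% by default.
* **Coefficient preset**: nonzero weights on age, BMI, blood pressure,
  parity, the history flags and higher-risk ethnic groups
  (`default_risk_coefficients()`). Magnitudes were fixed once so that a
  logistic model refit on a fresh cohort of 30,000 attains a held-out ROC
  AUC near 0.82 at the default prevalence — the discrimination level
  typical of first-trimester GDM models — and are not meant to be
  re-tuned per analysis.
* **Year structure**: records are assigned uniformly to 2018–2022 by
  default. `year_dip_multipliers()` reduces 2020's *ascertainment* to
  7.7/11.2 ≈ 0.69 of the other years: the multiplier scales the Bernoulli
  rate used to draw `true_label`, not the latent risk and not the feature
  distribution, matching the interpretation that pandemic-era screening
  changes suppressed diagnoses rather than risk. `true_risk` therefore
  always equals `plogis(linear_predictor)`.

Features are sampled independently; the only dependence in the data is
between features and outcome through the risk model. Real EHR cohorts have
correlated features (BMI with blood pressure, parity with age), repeat
pregnancies per patient, missingness, and noise mechanisms that depend on
features. Passing tests on this generator therefore demonstrates the
*mechanics* of label-noise effects — not that any particular hospital's
labels behave this way.

## The noise model

`corrupt_labels()` implements class-conditional "noise at random": given
rates `(fn_rate, fp_rate)`, it flips **exactly**
`round(fn_rate × #positives)` positives to 0 and
`round(fp_rate × #negatives)` negatives to 1 (round half away from zero),
drawn uniformly without replacement from the *original* classes. Exact
counts — rather than independent per-record coin flips — make the realized
discordance rates recoverable exactly by the validation metrics, which is
itself a test of the whole chain. Flip sets are disjoint by construction,
so the order of the two flip passes cannot matter. Each grid cell of a
sweep derives its own RNG stream from `(base_seed, fn_index, fp_index)`,
so any single cell is reproducible in isolation.

The defaults `fn_rate = 0.143, fp_rate = 0.023` are the discordance rates
observed when an EHR GDM flag is validated against a laboratory-confirmed
registry; at these rates about 3.5% of records carry a wrong label.

## Agreement metrics

`confusion()` counts TP/FP/TN/FN with the phenotype-validation convention
(observed = EHR, reference = registry). Rates divide by their natural
margins; a rate whose denominator is empty is reported as `NA` *and* named
in an `undefined` field — never silently propagated. Cohen's kappa uses
the two-rater form

$$\kappa = \frac{p_o - p_e}{1 - p_e},\qquad
  p_e = \frac{(tp+fp)(tp+fn) + (fn+tn)(fp+tn)}{n^2},$$

with the convention κ = 1 when both sources are constant and identical.
`stratified_report()` emits per-year rows, a pooled row, and an optional
pooled-without-one-stratum row (used to set 2020 aside). Internal values
are full precision; rounding to a table's printed precision happens only
at presentation.

## The modeling pipeline

* **Split**: 70/30, stratified on the reference label, with 2020 excluded
  by default (`split_plan()`). Stratification keeps a ~10%-prevalence test
  set from drifting; exclusion of the under-ascertained year avoids mixing
  a known labeling regime change into either side of the split.
* **Preprocessing** (`fit_preprocessor()`): one-hot encoding with the
  lexicographically smallest category dropped, and z-scoring with
  train-set means/SDs. All state is fitted on the training rows only; an
  unseen test category encodes as an all-zero block and a zero-variance
  numeric maps to 0.
* **Model** (`train_logistic()`): ridge-penalised logistic regression via
  glmnet with `alpha = 0`, penalty `lambda = 1/n` (the conventional
  unit-strength L2 default on glmnet's per-observation objective scale),
  intercept unpenalised, convergence threshold 1e-9 — all pinned in
  `logistic_config()` and recorded in the fitted model's metadata so
  "default hyperparameters" means the same thing in every run. glmnet is
  fit down a short decreasing lambda path and read off at the target:
  handing it a single small lambda is numerically unreliable, while warm
  starts are both stable and fast.
* **Discrimination**: `roc_auc()` is the Mann–Whitney statistic computed
  from midranks (ties credited 0.5); `average_precision()` is the
  step-wise precision-recall summary over descending unique thresholds
  with no interpolation, so it equals prevalence for constant scores.
  Both are checked in the test suite against brute-force pairwise /
  threshold-enumeration oracles.
* **AUC interval** (`auc_ci()`): label-stratified percentile bootstrap,
  2000 resamples by default. The resampling is stratified so no resample
  loses a class; percentile bounds are assumption-free and seeded.
* **Calibration** (`calibration_intercept_slope()`): logistic
  recalibration in the clinical-reporting convention — the slope is the
  coefficient of outcome on `logit(p̂)`, the intercept is
  calibration-in-the-large estimated with `logit(p̂)` as a fixed offset.
  Probabilities are clipped to `[1e-6, 1 − 1e-6]` before the logit so
  saturated predictions keep finite working values. Reliability curves use
  10 equal-frequency bins (quantile breaks, ties to the lower bin, empty
  bins dropped) — equal-width bins are unstable in the sparse upper tail
  of a skewed risk distribution.

### The three arms

`run_label_source_experiment()` runs, on one shared split:

| arm | trained on | evaluated on |
|---|---|---|
| `ehr_train_val_test` | all train rows, noisy labels | agreement test rows, validated labels |
| `val_train_val_test` | agreement train rows, validated labels | agreement test rows, validated labels |
| `val_train_ehr_test` | (same model as above) | all test rows, noisy labels |

A validated label exists only where the two sources agree, so the
validated arms necessarily use the agreement subset; the noisy-label arms
use all rows. This is the only self-consistent reading of a design in
which one model is trained on raw labels, one on validated labels, both
are compared on validated test labels, and the validated model is
additionally evaluated against raw test labels.

## Test-label noise has a closed form

For a *fixed* scorer, corrupting the test labels mixes the classes. With
prevalence π and rates `(fn, fp)`, let

$$a = P(\text{truly +}\mid\text{noisy +})
    = \frac{\pi(1-fn)}{\pi(1-fn) + (1-\pi)fp},\qquad
  b = P(\text{truly +}\mid\text{noisy −})
    = \frac{\pi\,fn}{\pi\,fn + (1-\pi)(1-fp)}.$$

A noisy-positive/noisy-negative score pair is two true positives with
probability `a·b` (AUC contribution ½), a true positive vs true negative
with probability `a(1−b)` (contribution = clean AUC), reversed with
probability `(1−a)b` (contribution = 1 − clean AUC), and two true
negatives otherwise (½). `expected_noisy_auc()` sums these four terms.
The identities — rates (0,0) return the clean AUC, rates (1,1) its
complement, and AUC ½ is invariant — plus agreement with large-sample
simulation within Monte-Carlo error are asserted in the test suite.

Two practical consequences the sweeps make visible:

* the expected AUC *declines* along the FP axis, steeply at first and then
  flatly (the noisy-positive class is quickly dominated by flipped
  negatives, after which further flips change little) — so at finite test
  sizes adjacent high-FP cells differ by less than Monte-Carlo noise, and
  the package's tests check monotonicity up to that noise rather than
  pretending the sample path is exact;
* average precision *rises* again at high FP rates: a random ranker's AP
  equals the prevalence of whatever labels score it, and
  `noisy_prevalence(0.105, 0, 0.9) ≈ 0.91` — flipping 90% of negatives
  turns a 90%-negative test set into a 90%-positive one, inflating the
  AP floor far above the clean value. The apparent "improvement" is
  class-balance inflation, not model quality.

## Sweeps

`run_train_noise_grid()` corrupts the *training* labels per cell, refits
preprocessing and model (preprocessing is refit for symmetry even though
labels never enter it), and reports metrics both against the cell's own
noisy training labels and against the untouched clean test set; the
default 10 × 10 grid trains 100 models. `run_test_noise_grid()` fits one
clean model and rescored its fixed test predictions against each cell's
corrupted labels. Both arms share the split and base seed, so their (0,0)
cells coincide exactly with the clean pipeline. A cell whose corrupted
labels collapse to one class is flagged undefined and skipped, not an
error. Matrices are written with FN levels as rows and FP levels as
columns, the orientation of the usual heatmap figures.

## Problem sizes

The package's own analyses and checks use cohorts of 20,000–50,000
synthetic pregnancies: large enough that binomial 3σ bands on prevalences
and marginals are tight and refit AUCs stabilise to ±0.01, small enough
that the full 100-fit sweep completes in about a minute on one core.
Cohort size is a single argument everywhere, so any analysis scales up
unchanged.

## Known limitations

* Features are mutually independent and one record is one patient; there
  is no visit structure, missingness, or within-patient correlation.
* Only noise-at-random is implemented: flips depend on the true class but
  not on features or predicted risk. Real EHR errors are plausibly
  feature-dependent.
* Only logistic regression ships as a learner; the evaluation functions
  accept any probability vector, so other models can be scored, but the
  sweep drivers refit logistic models only.
* The generator's 2020 dip scales diagnosed prevalence uniformly within
  the year; real screening disruption was concentrated in part of the
  year and may have shifted who was tested, not just how many.
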