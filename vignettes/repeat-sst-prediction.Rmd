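---
title: "Predicting repeat short Synacthen test results: models and methods"
author: "sstpredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting repeat short Synacthen test results: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sstpredict)
```

## The clinical problem

The 250-µg short Synacthen test (SST, also called the ACTH stimulation
test) is the standard dynamic test for adrenal insufficiency: serum
cortisol is measured at baseline and 30 minutes after injection of
synthetic ACTH, and a 30-minute cortisol at or above an assay-specific
threshold (430 nmol/L here) classifies the patient as adrenally
sufficient. Patients weaning from glucocorticoids are often retested
repeatedly while their hypothalamic–pituitary–adrenal axis recovers,
which is burdensome for patients and services alike.

`sstpredict` implements prediction models for the *next* test's
30-minute cortisol from information available before stimulation: the
new early-morning baseline cortisol, optionally combined with the
patient's previous SST results. If the prediction is confidently low or
confidently high, the dynamic test itself can be skipped.

## The models

Both shipped models are fractional-polynomial (FP1) linear models on
scaled covariates:

* **morning_only**: 30-min cortisol = −54.476 + 325.134 √(new baseline
  cortisol / 100), residual SD 110.3 nmol/L.
* **previous_ast**: 30-min cortisol = −116.5 + 251.5 √(new baseline
  cortisol / 100) − 49.4 (previous baseline cortisol / 100) + 714.3
  (previous 30-minute cortisol / 1000), residual SD 73.4 nmol/L.

All cortisol values are nmol/L; ACTH, where used as a candidate, is
ng/L. The square-root shape captures the decelerating relationship
between baseline and stimulated cortisol; the previous test's baseline
enters negatively because, at a fixed previous 30-minute response, a
higher previous baseline means the previous increment was smaller.

Predictions convert to a pass probability by treating the outcome as
Gaussian around the point prediction with the model's residual SD:
`pass_probability(point, residual_sd, threshold)`. A point prediction
exactly at the threshold therefore corresponds to a 50% chance of
passing.

One documented quirk: solving the morning-only formula for the baseline
cortisol that predicts exactly 430 nmol/L gives ≈ 222 nmol/L
(`invert_covariate(published_models()$morning_only, 430,
"new_baseline_cortisol")`), not the 133 nmol/L sometimes quoted
alongside these coefficients. The package follows the printed
coefficients and exposes the inversion rather than hard-coding either
number.

## The development procedure

`sst_develop()` re-implements the full development pipeline so it can be
studied and validated on synthetic cohorts:

1. **Bootstrap replication.** The development table is resampled with
   replacement `n_bootstrap` times (default 5000; simulation studies in
   this package typically use 100–200). Replicate seeds are derived from
   the master seed by a counter scheme, so results do not depend on
   execution order.
2. **Imputation.** Missing ACTH values are imputed within each replicate
   by chained random-forest regression (`ranger`, 100 trees, 2 sweeps);
   cortisol/ACTH ratios are recomputed from the imputed parents, never
   imputed directly.
3. **Transform choice.** Each candidate's FP1 power is chosen from
   {−2, −1, −0.5, 0, 0.5, 1, 2, 3} (0 = log) to minimise the residual
   sum of squares *of the full multivariable candidate model*, cycling
   over variables until stable, with ties broken toward linearity. We
   deliberately use this adjusted (MFP-style) search rather than a
   univariable one: with realistically correlated covariates, the
   univariable relationship between the outcome and one predictor is
   contaminated by the conditional means of the others, and the
   univariable search systematically mis-identifies the generating
   power (it prefers √ or log for the previous baseline cortisol even
   when the generating term is linear). The univariable criterion is
   still available as `select_fp_power()`.
4. **Backwards selection.** Terms are removed one at a time, largest
   p-value first, while that p-value exceeds `alpha` (0.05), refitting
   after each removal. If a replicate's fit is numerically perfect
   (relative residual sum of squares below machine-level tolerance),
   t-statistics are meaningless; significance then falls back to a
   drop-one comparison: a term is significant exactly when removing it
   destroys the fit. This keeps the procedure well-defined on noise-free
   simulated data.
5. **Parameter-wise shrinkage.** Named but not defined by a formula in
   most applied reports, implemented here as the standard
   cross-validation-calibration estimator: refit on each of K = 10
   training folds, compute per-term contributions (coefficient ×
   transformed covariate) for the held-out fold, then regress the
   held-out outcomes jointly on the contribution columns. The
   calibration slopes are the per-term shrinkage factors; shrunken
   coefficient = raw × factor, and the intercept is re-estimated so
   shrunken predictions are mean-unbiased.
6. **Aggregation.** A candidate enters the final model if its bootstrap
   inclusion fraction (share of replicates where it survived selection
   with p ≤ alpha) is at least 0.9. Its final power is the modal
   selected power and its coefficient the mean shrunken coefficient over
   replicates that selected that power — coefficients on different
   transforms of the same variable are not commensurable and are never
   averaged together. For the same reason the final intercept averages
   only over replicates whose selections are compatible with the final
   parameterisation (every final variable at its modal power); when no
   replicate qualifies, the intercept is recalibrated on the development
   data. When power choice is stable across replicates — the typical
   case — this equals the plain mean over all replicates. The residual
   SD is the final model's RMSE on the development table.

Two procedural details are genuinely underdetermined by the usual
description of such pipelines, and we fixed them as follows: variables
are removed one at a time (not all non-significant ones at once), and
shrinkage is estimated within each replicate (not once on the original
data), consistent with repeating the whole process per bootstrap
version.

## Performance statistics

`calibration_stats()` reports R² = 1 − SSE/SST (negative values possible
on external data), RMSE, and the calibration slope and intercept from
regressing observed on predicted (ideal 1 and 0; slope below 1 indicates
overfitting). `auc_at_threshold()` dichotomises the observed outcome at
the pass threshold and computes the Mann–Whitney concordance probability
with ties counting one half; it is tested against an O(n²) pairwise
enumeration and against an established ROC implementation. Confidence
intervals are percentile bootstrap (default 2000 resamples of
observation pairs) — the CI construction is a package choice, since
applied reports rarely state one. `cross_validate_groups()` performs
leave-one-group-out validation over sex, AI type or steroid treatment,
redeveloping the model on the complement each time;
`compare_models()` compares nested models by the likelihood-ratio
statistic n·ln(SSE_a/SSE_b) and the increment in R².

## The equivocal-range policy

`benefit_policy()` quantifies how many stimulation tests a
prediction-guided pathway would avoid. Operating characteristics are
those of the pass-detection rule "prediction > t": sensitivity(t) is the
fraction of observed passes predicted above t, specificity(t) the
fraction of observed fails predicted at or below t. The low threshold is
the *largest* t whose sensitivity still reaches the target (default
0.95): below it, at most 5% of true passes occur, so such predictions
are acted on as adrenal insufficiency. The high threshold is the
*smallest* t whose specificity reaches its target: above it, at most 5%
of true fails occur, so such predictions are accepted as adequate
function. Predictions strictly between the thresholds are equivocal and
proceed to an actual test; ties sit in the equivocal range
(conservative — borderline patients still get tested), so the saved and
equivocal fractions always sum to one exactly. Candidate thresholds are
midpoints between consecutive sorted unique predictions plus sentinels,
which keeps the search independent of the observed outcome values; both
searches are verified against a brute-force enumeration oracle. A very
accurate model can make the two thresholds cross; the policy then
collapses both to their midpoint (empty equivocal range) and flags it.

## The synthetic cohort generator

No patient-level data are distributed or downloadable, so every
downstream stage is exercised on synthetic paired-test cohorts from
`generate_cohort()`:

* **Marginals.** Hormone concentrations and days between tests are
  right-skewed and positive, so each is drawn from a log-normal
  truncated to the published observed range, with (µ, σ) solved
  numerically so the *truncated* distribution matches the published
  mean and SD. The packaged defaults encode the development cohort's
  descriptive statistics (e.g. previous baseline cortisol 186.0 ± 109.9,
  range 2–664 nmol/L; 258 pairs).
* **Dependence.** A Gaussian copula on the latent normal scale links
  previous baseline cortisol to previous 30-minute cortisol and to new
  baseline cortisol (correlation 0.7 each, hence 0.49 between the
  latter two), and each ACTH value to its same-test cortisol (0.3).
  No covariance matrix was ever published for these variables, so the
  copula correlation is a modelling choice, not a reproduced value;
  0.7 was fixed once because it reproduces the qualitative fact that
  previous-test information explains substantially more outcome
  variance than the new baseline alone, and it was not revisited.
* **Outcome.** The new 30-minute cortisol is the previous-AST model's
  linear predictor plus Gaussian noise with SD 73.4 nmol/L (the
  development RMSE), clipped at zero. Clipping affects well under 1% of
  draws at the default settings.
* **Missingness.** ACTH is set missing completely at random at rate
  0.081 (≈ 21/258), matching the published missing-value counts; no
  mechanism beyond MCAR was reported.
* **Group labels.** Sex, AI type and steroid route/formulation are
  sampled independently of the hormone values at the published
  proportions. They exist to exercise cross-validation plumbing; the
  generator encodes no stratum-specific biology, so grouped
  cross-validation on synthetic data checks machinery, not clinical
  heterogeneity.

What passing tests on these cohorts demonstrates is therefore limited:
the pipeline recovers known generating mechanisms, the statistics agree
with independent oracles, and the previous-AST model dominates the
morning-only model under the stated generating mechanism. They cannot
re-establish the real-data performance figures, which require the
original patient records.

## Numerical choices and problem sizes

Bisection for `invert_covariate()` runs on [0, 2000] nmol/L to an
absolute tolerance of 1e-6. Plausibility windows (cortisol ≤ 2000
nmol/L, ACTH ≤ 500 ng/L) produce warnings, not errors — published
ranges are sample ranges, not physiological limits. Point predictions
are never clipped at zero internally (clipping would bias calibration
statistics); only the command-line calculator floors its rounded
user-facing output at zero. The test suite exercises the pipeline at
reduced but structurally faithful sizes chosen as a deliberate
simulation design: cohorts of 80–500 pairs with 10–200 bootstrap
replicates for pipeline behaviour, 10,000 pairs for coefficient
recovery, and 100,000 draws for marginal-moment checks.

## Limitations

The generator emulates marginal moments, ranges, one plausible
dependence structure and MCAR missingness — not assay changes,
time-of-day effects, within-patient series longer than one pair, or
stratum-specific outcome mechanisms. The shrinkage estimator and the
CI construction are reasonable standard choices where the original
procedure is not fully specified; both are isolated behind their own
functions so alternatives can be swapped in. Models developed on one
assay do not transfer to another without recalibration, and the shipped
coefficients assume cortisol measured on the assay they were developed
on.
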