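---
title: "Shared cortical-thickness abnormality patterns: the ctensemble pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared cortical-thickness abnormality patterns: the ctensemble pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctensemble)
```

## The scientific question

Treatment-resistant schizophrenia (TRS) and antipsychotic-responsive
schizophrenia (NTRS) may be distinct disease entities or points on one
continuum.  One way to make that question operational with structural MRI is
*classifier exchangeability*: build an ensemble classifier that separates
NTRS patients from healthy controls (HC) using region-wise cortical
thickness, build a second one for TRS, then apply each ensemble to the
*other* patient group.  If the NTRS-trained ensemble also separates TRS
patients from controls (and vice versa), the two groups plausibly share a
cortical abnormality pattern; if cross-applied performance collapses, their
patterns are dissociable.  `ctensemble` implements that full inferential
procedure — harmonization, ensemble construction, cross-application, and
permutation inference — as a tested pipeline driven by a synthetic cohort
generator with known ground truth.

## The synthetic cohort generator

No clinical MRI data ship with this package; every stage is instead
exercised on cohorts drawn from an explicit generative model
(`cohort_spec()` / `generate_cohort()`).  Thickness at ROI $r$ for subject
$i$ in group $g$ at site $s$ is

$$t_{ir} = \mu + \beta_{\mathrm{age}}(\mathrm{age}_i - 42) - d_{gr}\,\sigma +
  \mathrm{shift}_s + u_{sr} + \varepsilon_{ir},\qquad
  \varepsilon_{ir}\sim N\!\big(0, (\sigma c_s)^2\big)$$

with defaults chosen once as plausible study conditions:

* $\mu = 2.5$ mm, $\sigma = 0.25$ mm — typical cortical thickness scale;
* group sizes 52 HC / 46 NTRS / 64 TRS across two sites (27/28/20 and
  25/18/44), the split of the motivating study apportioned by enrollment;
* age $\sim N(42, 12^2)$ truncated to 18–75, 40% female, education
  $\sim N(13.5, 2.5^2)$ years, and an age slope of $-0.003$ mm/year applied
  to all ROIs, so harmonization has genuine biological covariates to
  preserve;
* site effects: a deterministic per-site offset `site_shift` (mm) plus
  zero-mean per-site per-ROI offsets $u_{sr}$ with SD `site_roi_sd`
  (default 0.05 mm) and a multiplicative noise factor $c_s$ — exactly the
  additive-location / multiplicative-scale family empirical-Bayes
  harmonization assumes, so recovery is testable.  The deterministic offset
  (rather than only random per-ROI draws) makes "inject +0.2 mm at site B,
  verify it is removed" a sharp oracle;
* deficits are sparse and group-specific: `effect_map` lists
  (ROI, group, $d$) triples, each shifting that group's mean down by
  $d\sigma$, so the planted population Cohen's $d$ equals $d$ at unit site
  scale.  `default_effect_map()` plants a broadly shared pattern — both
  patient groups thinner at six regions (left planum temporale, anterior
  insula/IFG, supramarginal gyrus, IFG; right anterior STS, lateral OFC) —
  with the right-hemisphere deficits much stronger in the resistant group
  (its two effectively unique regions) and the supramarginal deficit weak
  there.  No published per-region effect sizes exist to copy, so the
  magnitudes ($d$ of 0.3–1.0) were calibrated once so that the default
  two-site study produces direct and cross-applied ensemble AUCs in the
  reported ranges (about 0.7 responsive, 0.85 resistant, 0.7–0.78
  cross-applied) — the only quantitative anchors available — and were not
  revisited.

ROIs are independent by default (an optional equicorrelation `rho` exists).
Real cortical data have spatially correlated parcels, site effects that need
not follow the assumed location-scale family, and non-Gaussian tails; a
passing test suite therefore certifies the *machinery* — recovery of known
structure under the model's assumptions — not performance on clinical data.

## Harmonization

`fit_combat()` implements the parametric empirical-Bayes location-scale
harmonization of Johnson, Li & Rabinovic (2007): per-ROI linear model with
site indicators and biological covariates, standardization by the
covariate-adjusted pooled SD, method-of-moments hyperpriors, and the
iterative posterior solution for per-site location ($\gamma^*$) and scale
($\delta^*$) effects.  `apply_combat()` then maps each value through
$(z - \gamma^*_s)/\sqrt{\delta^*_s}$ and restores the covariate-predicted
mean.  The implementation is authored in-package because the pipeline needs
a fit/apply split with auditable, serializable per-site parameters and hard
errors on unseen sites; on a shared fit-and-transform task it reproduces
`sva::ComBat` to numerical precision (asserted in the test suite).

Two deliberate design points:

* **Three-group status coding.**  Diagnostic status enters the design as
  HC/NTRS/TRS (two indicators), never as a collapsed patient column, by
  default.  Collapsing would let harmonization absorb between-patient-group
  differences — the very signal the downstream question is about — so the
  two-group coding sits behind an explicit override.
* **Harmonize once, before cross-validation.**  The model is fitted on the
  full cohort prior to classification, matching the procedure this package
  operationalizes; the leakage mitigation is the three-group coding, not
  within-fold refitting.  This is a known departure from strict CV hygiene
  and is kept deliberately, faithful to the published order of operations.

Education enters as years (the coarser-scale alternative is not modeled).

## The classifier core

Each classifier is an L1-penalized logistic regression minimizing

$$J(w, b) = -\frac{1}{n}\sum_{i=1}^n \log P(y_i \mid x_i; w, b) +
  \lambda\lVert w\rVert_1$$

with an unpenalized intercept, solved by iteratively reweighted least
squares with cyclic coordinate descent (compiled code, warm-started along
the penalty path, safeguarded so the objective never increases).  Features
are z-scored within each training set; test subjects reuse the training
parameters.  The solver's optimality is certified two ways in the tests: a
dense-grid oracle on tiny instances and the KKT stationarity conditions
(complete for this convex problem) at every returned fit, plus an
independent cross-check against `glmnet` at matched penalties.

The penalty grid is **25 values spaced linearly on $(0, \lambda_{\max}]$**,
where $\lambda_{\max} = \max_j |n^{-1}\sum_i x_{ij}(y_i - \bar y)|$ is the
smallest penalty whose only solution is the zero vector.  Linear spacing
follows the procedure's stated construction; the geometric spacing common in
lasso software is available via `lambda_spacing = "geometric"` for
sensitivity analysis.  The penalty is tuned by stratified inner 10-fold
cross-validation on mean binomial deviance with the **one-standard-error
rule**: the largest (sparsest) penalty whose mean deviance lies within one
band of the minimum.  The band is the SE of the fold deviances
($\mathrm{SD}/\sqrt{k}$, the rule's standard definition); whether the
original analysis used SD or SE cannot be determined from its description,
so `one_se_band = "sd"` exposes the alternative.  Ties resolve toward the
larger penalty.

## The ensemble pipeline

`run_nested_cv()` wraps the core in stratified nested 10-fold
cross-validation.  Within each outer loop, training data are the other nine
folds' controls plus the contrast's patient group.  Because HC/patient
counts are imbalanced, the majority class is randomly undersampled to the
minority's size — whichever side is larger — and this subsampling repeats
ten times, yielding ten tuned classifiers per fold (100 per contrast).
Held-out subjects receive the **soft vote**: the mean of the ten members'
predicted probabilities, the "diagnostic probability".  A subject is called
a patient when it exceeds 0.5 (ties classify as control).  Training HCs are
shared by both contrasts' classifiers; splitting the controls between
contrasts would starve both, and the leakage being guarded is train/test,
not HC reuse.

Each fold's ensemble also scores the held-out fold's *other* patient group,
so `cross_apply()` can assemble the exchangeability readout without any
refitting — and provably without ever scoring a subject by an ensemble that
trained on it (asserted programmatically).  AUC is computed from the
aggregated out-of-fold probabilities as the Mann-Whitney rank statistic
(hard labels alone cannot yield an AUC); accuracy, sensitivity and
specificity come from the confusion matrix at the threshold.

All randomness — fold assignment, undersampling, inner folds, permutations —
derives from one master seed through `derive_seed()`, so the entire analysis
is a pure function of (data, config).

## Permutation inference

`permutation_null()` shuffles the diagnosis labels of the whole cohort
(jointly across sites; harmonization is not refit, matching the pipeline's
order of operations) and reruns the *identical* two-contrast pipeline — the
permutation engine literally calls the same nested-CV code path.  Two
max-statistic null distributions come from the same reruns:

* **AUC**: the per-iteration maximum of the two contrasts' AUCs; every
  observed AUC (direct and cross-applied) is tested one-sided against it.
* **Selection frequency**: how often each ROI received a nonzero weight
  across the 100 fits.  The default null statistic is the maximum count over
  *all ROIs and both contrasts*: the stated purpose of the correction is the
  multiple-comparison problem across regions, and only a max over regions
  controls family-wise error there.  A narrower contrasts-only variant
  (per-ROI null of the two contrasts' maximum) is available via
  `scope = "contrasts"` since the original description is ambiguous about
  the region dimension.

p-values use the add-one estimator $(1 + \#\{\text{null} \ge
\text{obs}\})/(1 + B)$, never exactly zero.  Each permutation iteration
re-tunes the penalty end to end — the full inner CV runs under every
permutation.  Effect sizes for flagged regions are Cohen's $d$ with pooled
SD (patient minus control, negative = thinner), with plain pooled two-sample
t-tests for group-pair significance; the original post-hoc test is not
stated, so this is a documented assumption.

## Numerical choices and degenerate inputs

* Solver: objective tolerance $10^{-9}$ for direct fits (contract
  $10^{-7}$); a KKT check (tolerance $10^{-6}$) gates convergence.  Weights
  below $10^{-10}$ snap to zero so that fits at $\lambda \ge \lambda_{\max}$
  are exactly empty despite floating-point roundoff at the KKT boundary.
* Ensemble internals run the penalty path at slightly looser tolerances
  (objective $10^{-7}$ for kept fits, $10^{-4}$ for inner-CV deviance
  estimates).  Deviance curves are insensitive at that level, and
  permutation calibration is unaffected by construction: observed and
  permuted runs share the identical configuration, so under the null they
  remain exchangeable whatever the fit tolerance.
* A subsample whose $\lambda_{\max}$ is zero (no feature covaries with the
  labels) contributes an intercept-only member rather than failing.
* Constant features are dropped with a warning at standardization; fewer
  subjects than folds, single-class folds, single-site harmonization, and
  unseen site labels are hard errors.

## Problem sizes in the test suite

The packaged tests exercise the pipeline at deliberately reduced scale —
cohorts of 50 per group, 100 ROIs, 3–5 outer folds, 2–5 subsamples, and
29–99 permutations — sizes chosen so the full suite, including two
simulation studies (null calibration across 20 cohorts; signal recovery
across 10), completes on a single CPU while leaving the statistical
assertions sharp.  `scripts/acceptance.R` runs the full-design study (400
ROIs, 10 outer folds, 10 subsamples, 29 permutations) once, end to end.
The vignette's claims about behavior are exactly those the tests compute;
no result here is asserted beyond what the suite verifies.

## Known limitations

* The generator's independence-across-ROIs default understates the spatial
  correlation of real cortical parcels; planted-support recovery results are
  correspondingly optimistic.
* Harmonization assumes the location-scale site model; scanner effects that
  alter covariances or interact with diagnosis are outside it.
* The ensemble exists only inside the cross-validation; no persisted model
  for deploying on new cohorts is produced.
* No vertex-wise analysis, no longitudinal harmonization, no symptom-scale
  correlation analyses.
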