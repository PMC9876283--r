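---
title: "Validating VO2max prediction equations in endurance athletes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating VO2max prediction equations in endurance athletes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vo2val)
```

## The problem

Maximal oxygen uptake (VO2max) is the reference measure of
cardiorespiratory fitness, but its direct measurement requires a maximal
cardiopulmonary exercise test (CPET) with breath-by-breath gas exchange
analysis.  Many prediction equations estimate VO2max from age, sex, body
mass and related covariates instead.  Most of these equations were
derived on general or clinical populations; whether they transfer to
endurance athletes — runners and cyclists whose fitness sits well above
population norms — is an external-validation question.

`vo2val` implements that validation as a reusable pipeline: eligibility
filtering of CPET records, stratification by age and endurance level,
uniform evaluation of a registry of prediction equations, and
calibration metrics in the TRIPOD tradition.  Because clinical CPET
data of this kind are rarely shareable, the package also ships a
synthetic cohort generator calibrated to published population
parameters of a large athlete cohort, so every stage is testable
end-to-end without any external data.

## The measurement model

A CPET ends at volitional exhaustion; VO2max is taken as the highest
15-second averaged oxygen uptake at the end of the test.
`vo2max_15s()` implements this reduction for irregular breath-by-breath
series: each breath's value is held until the next breath (a step
function), and the statistic is the maximum over all 15-s windows of
the time-weighted mean.  The window is *sliding*, not binned: the
windowed integral of a step function is piecewise linear in the window
start, so its maximum is attained with a window edge at a breath time
and only those candidate starts need evaluation.  Fixed contiguous bins
would be an equally defensible reading of "15-s averaging"; the sliding
window is the more conservative (never smaller) statistic and is the
package's choice.

Records store relative VO2max (mL·min⁻¹·kg⁻¹) as primary; absolute
values (mL·min⁻¹ or L·min⁻¹) are always derived via body mass
(`convert_vo2()`), never stored, so the two can not disagree.

## Eligibility

Inclusion requires: ≥ 3 months of regular running or cycling training,
age ≥ 18 years, no medical condition or medication, non-smoker, no
variable beyond ±3 SD of the cohort mean (extreme-outlier screen), and
evidence of maximal exertion.  Maximal exertion is defined as meeting
at least 6 of 7 criteria, all inclusive at the boundary:

1. respiratory exchange ratio ≥ 1.10;
2. a VO2 plateau (growth < 100 mL·min⁻¹ despite increased intensity);
3. breathing frequency ≥ 45 breaths·min⁻¹;
4. Borg rating of perceived exertion ≥ 18;
5. blood lactate ≥ 8 mmol·L⁻¹;
6. speed/power gain ≥ 10% beyond the respiratory compensation point;
7. peak heart rate within 15 bpm of predicted maximum.

Three points here were genuinely open and are package decisions:

* **Predicted HRmax.**  No formula is attached to criterion 7 in the
  source tradition; the package defaults to the classical 220 − age
  (`"fox"`), with Tanaka's 208 − 0.7·age available.
* **Direction of criterion 7.**  Read literally, "HR_peak ≥ 15 bpm
  below predicted maximum" would reward *low* heart rates, contradicting
  a maximal-effort criterion; the package reads it as
  `HR_peak ≥ HRmax_pred − 15`.
* **Outlier screen.**  "All testing variables" is interpreted as
  `r paste(outlier_default_variables(), collapse = ", ")`, with moments
  computed within sex, in a single non-iterative pass (iterative
  re-screening would change n and is not part of the procedure).  The
  screen runs before the effort filter; both the variable set and the
  moments are arguments, so the order can be changed and a second pass
  can reuse the first pass's moments — which is exactly what makes
  filtering idempotent.

A missing criterion field counts as "not met" and is flagged, rather
than raising an error: a record with 6 intact criteria can still pass.

## Stratification

Age groups are 18–30, 31–45, 46–60 and ≥ 61 completed years (ages are
truncated to whole years before bucketing, so 30.9 is "18–30").

Endurance groups are SD bands of the variable most closely tied to
critical endurance capacity: speed (km·h⁻¹) at the respiratory
compensation point for treadmill tests, relative power (W·kg⁻¹) for
cycle-ergometer tests.  Using an RCP variable rather than VO2max itself
keeps the grouping independent of the quantity being validated.
Z-scores are computed within sex × modality — the source convention
states "within each sex", but speed and W·kg⁻¹ are incommensurable, so
pooling modalities is impossible and the within-modality refinement is
forced; this is a documented deviation surface.  The bands are:

* HTEA (high-trained), z > 1.5;
* LTEA (low-trained), z < −1.5;
* REA (recreational), |z| < 0.5;
* "transition", 0.5 ≤ |z| ≤ 1.5 — the printed inequality directions put
  the boundary values ±0.5 and ±1.5 themselves in transition.

Under a normal RCP distribution the expected shares are
P(|Z| < 0.5) ≈ 38.3% REA and P(Z < −1.5) ≈ 6.7% LTEA, matching the
reference cohort's printed 38.19% and 6.56% within sampling error — a
property the acceptance suite verifies by simulation.  Validation is
run per subgroup except transition, which only enters whole-population
panels; subgroups below n = 100 are flagged as unreliable per the
TRIPOD sample-size guideline.

## The equation registry

`builtin_models()` returns 13 equations from 8 publications, each a
self-contained specification: applicability by sex and modality, native
output unit, predictor list, and a pure evaluation function.  The row
structure mirrors the published validation panels: a male-only and a
female-only meta-analysis equation (Wilson; Fitzgerald), sex-specific
clinical reference equations (Wasserman, counted per sex), three
cycle-ergometer equations from one registry source (male, female,
combined), a cycle-ergometer population reference (Mylius), a treadmill
population reference (Myers), two treadmill equations from one
allometric-modelling source, and two athlete-derived equations (Petek,
treadmill and cycle ergometer, in L·min⁻¹).

Two contracts are enforced mechanically.  *Unit discipline*: the
observed value is converted to each model's native unit before any
comparison, so no metric ever mixes units.  *Applicability closure*: no
prediction is produced outside a model's declared sex × modality sets;
non-applicable cells are flagged, never zero-filled.

Out-of-range inputs (an age beyond an equation's derivation range, for
instance) yield a prediction with a flag rather than a refusal,
mirroring cohort-wide application in practice.  The built-in
coefficient values are transcriptions of the cited equations; they
should be audited against the primary publications before any clinical
use, and `register()` / `linear_vo2_model()` exist precisely so a
corrected or additional equation can be swapped in without touching the
validation engine.

## Calibration metrics

For each model × subgroup, `fit_calibration()` regresses observed on
predicted by ordinary least squares and reports:

* **calibration slope (C2)** — the OLS slope, 1 ideal;
* **calibration-in-the-large (C1)** — by default the free intercept of
  that regression, 0 ideal; the mean-difference convention
  `mean(observed) − mean(predicted)` is also implemented, and every
  result is convention-tagged.  The two coincide only when the slope
  is 1.  The free-intercept convention is the default because it is the
  one whose magnitudes match tabulated validation reports that print an
  intercept-type statistic next to a slope near 1 (intercepts in the
  thousands of mL·min⁻¹ for absolute-unit models);
* **adjusted R²** — `1 − (1 − R²)(n − 1)/(n − 2)`, which can be
  negative for uncorrelated pairs, with effect-size classes < 0.3
  none/very weak, 0.3–0.5 weak/low, 0.5–0.7 moderate, > 0.7 high;
* **RMSE** — root mean squared residual of the calibration fit;
* **paired mean difference** (predicted − observed, positive =
  overestimation) with a two-sided t-based 95% CI.

Significance of C2 and C1 is assessed by the coefficient Wald tests of
the calibration regression (or the paired t-test under the
mean-difference convention); no multiple-testing correction is applied
by default.  Degenerate cells — empty subgroups, n < 3, constant
predictions — are emitted with explicit status markers rather than
dropped.  When paired differences have zero variance the t statistic is
undefined; the p-value is reported as 1 for perfect agreement and `NA`
for a constant non-zero offset.

```{r calibration-example}
co <- stratify(apply_inclusion(generate_cohort(default_config(2000, seed = 7)))$cohort)
metrics <- validate_models(co, axis = "endurance")
head(metrics[metrics$status == "ok",
             c("model_id", "sex", "modality", "subgroup", "n",
               "r2_adj", "rmse", "c1", "c2")])
```

## The synthetic cohort generator

`default_config()` encodes the reference population: 84.76% male; male
age 35.04 (9.58) y, height 179.42 (6.60) cm, mass 77.23 (10.32) kg,
body fat 15.68 (4.55)%; female age 32.25 (8.99) y, height 167.19
(6.88) cm, mass 60.60 (8.73) kg, body fat 22.04 (5.46)%; treadmill
shares 3330/4459 (male) and 671/801 (female); VO2max means (SD) of
54.10 (6.93), 51.92 (8.05), 48.79 (6.67) and 49.05 (6.64)
mL·min⁻¹·kg⁻¹ for male-TE, male-CE, female-TE and female-CE.

Design of the generator:

* **Truncated normal margins with location correction.**  Age is
  truncated at 18 (height, mass and body fat at physiologic floors);
  naive truncation would inflate the mean, so the location parameter is
  solved (by `uniroot` on the truncated-normal mean) such that the
  *realized* mean equals the configured one.  The configured SD is used
  as the scale parameter; realized SDs are therefore slightly below
  nominal where truncation bites (a few percent for age).  Means are
  exact in expectation — the property the acceptance suite checks at
  n = 100,000 within 4 standard errors.
* **Gaussian copula dependence.**  A latent fitness variable correlates
  −0.4 with age and drives VO2max; the RCP variable loads on latent
  fitness with correlation 0.9 within each sex × modality stratum.
  Both magnitudes are generator conventions chosen as physiologically
  plausible (fitness declines with age; RCP speed/power is a strong
  but imperfect proxy of VO2max), not published estimates.  On the
  observed scale the age correlation is attenuated by the truncated
  margin; rank correlations survive the monotone transform, which is
  how the tests verify it.
* **Effort variables** default to passing distributions — RER
  N(1.14, 0.04), lactate N(10, 2), breathing frequency N(55, 8), Borg
  uniform on {18, 19, 20}, HR deficit |N(5, 5)| bpm below predicted
  maximum, post-RCP gain N(15, 3)%, plateau probability 0.95.  These
  tails mean roughly 10–15% of a "clean" cohort still fails the
  ≥ 6-of-7 rule, which is the realistic regime: the reference intake
  excluded a comparable fraction.
* **Fat-free mass is computed**, never sampled
  (`mass · (1 − bf/100)`), so the record-level consistency invariant
  holds exactly, at the cost of small divergence from published FFM
  SDs.
* **Determinism.**  All draws are vectorized in fixed order under one
  seed; identical (config, seed) gives byte-identical cohorts.

`contaminate()` injects named eligibility violations (one per record)
for round-trip testing of the filter; because a single unmet exertion
criterion does not by itself fail the ≥ 6-of-7 rule, effort-type
defects are asserted at the per-criterion assessment level, while
inclusion-type defects (age, smoker, outlier) are asserted as actual
exclusions with matching reason codes.  `inject_predictions()` builds
(observed, predicted) pairs with a known calibration defect
`observed = c0 + c1·predicted + N(0, σ)`; the noise is drawn
independently of the predictor, so the calibration regression is
consistent for (c0, c1) and parameter recovery is a sharp test.

What the generator does *not* emulate: breath-by-breath traces for
every athlete (series are built on demand in tests), training-history
dynamics, seasonal effects, inter-equipment variation, or any
non-Gaussian features of real CPET marginals.  Passing tests therefore
demonstrate the correctness of the pipeline's logic and metrics on
data with the assumed structure — not the field accuracy of any
equation on real athletes.

## Numerical choices and edge cases

* Calibration fits require n ≥ 3 and non-constant predictions; below
  that, rows carry `"degenerate"`/`"empty"` status markers.
* Unit conversions pivot through mL·min⁻¹ and round-trip to within
  1e-9 relative over arbitrary cycles.
* The 15-s reducer requires a series spanning at least the window and
  errors otherwise; window length is an argument (15 s default) and is
  recorded in pipeline manifests.
* Zero-variance variables in the outlier screen are skipped with a
  warning, not an error.
* Age groups reject ages below 18 (such records are excluded upstream).

## Problem sizes

The test-suite simulations use cohorts of 400–20,000 records for
distributional checks, 100,000 for the generator-calibration
acceptance check, one million draws for the endurance-band tail-share
check, and 200 replicates of n = 5,000 for calibration-defect
recovery.  These sizes put Monte-Carlo error well below the asserted
tolerances while keeping the default suite fast on a single CPU.

## Known limitations

* Built-in coefficients are registry transcriptions; audit before
  clinical use (see above).
* The generator's dependence magnitudes are conventions; subgroup-level
  R² values on synthetic cohorts are structurally, not numerically,
  comparable to published validations of real athletes.
* Whole-cohort headline metrics from any specific published validation
  depend on that study's undeposited data and are out of reach by
  design; the package validates the *method*, and applies it to
  whatever cohort the user supplies.
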