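---
title: "Soil-wheat cadmium transfer models and safe-production thresholds: methods"
author: "cdwheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil-wheat cadmium transfer models and safe-production thresholds: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdwheat)
```

## The problem

Wheat accumulates cadmium (Cd) from soil more readily than most staple
cereals, so a soil that is legal for agriculture can still produce grain
above the food-safety limit of 0.1 mg/kg Cd. Regulators deal with this
through stepwise soil quality standards — a fixed total-Cd limit per soil pH
band — but a step function ignores how strongly transfer depends on soil
chemistry. `cdwheat` implements the alternative: fit a quantitative transfer
model from paired soil-grain survey data, invert it at the grain limit to
obtain a *continuous* soil Cd threshold as a function of pH (and CEC), and
score any rule — derived curve or official step standard — by how accurately
it separates fields that actually produce exceeding grain from those that do
not.

## The transfer models

The analysis unit is a paired record: one soil sample (pH, CEC in cmol/kg,
clay %, SOM g/kg, DCB-extractable and oxalate-extractable Fe in g/kg, total
Cd, optionally CaCl2-extractable Cd and model-dissolved Cd) together with the
Cd content of the wheat grain grown on it. The derived bioconcentration
factor is

$$\mathrm{BCF} = \mathrm{Cd}_{wheat} / \mathrm{Cd}_{soil},$$

a dimensionless measure of transfer. The model suite (`cd_model()`) consists
of log-linear regressions on base-10 logarithms:

* **M1**: $\log_{10} \mathrm{Cd}_{wheat} = 0.906\,\log_{10}\mathrm{Cd}_{soil} - 0.718$
* **M2**: $\log_{10} \mathrm{Cd}_{wheat} = 0.955\,\log_{10}\mathrm{Cd}_{soil} - 0.118\,\mathrm{pH} - 0.010\,\mathrm{CEC} + 0.114$
* **M3**: $\mathrm{Cd}_{wheat} = \mathrm{BCF}(\mathrm{pH}) \cdot \mathrm{Cd}_{soil}$, with $\mathrm{BCF}(\mathrm{pH}) = 0.014\,\mathrm{pH}^2 - 0.236\,\mathrm{pH} + 1.113$
* **M4**: $\log_{10} \mathrm{Cd}_{wheat} = 0.509\,\log_{10}\mathrm{Cd}_{CaCl_2} + 0.104\,\mathrm{pH} - 0.768$
* **M5 / M5star**: the same form on the model-dissolved Cd pool (mg/L at a
  1:10 solid-liquid ratio).

Logs are base 10 throughout: the package's threshold arithmetic only
reproduces the published threshold table in base 10 (e.g. inverting M1 at
0.1 mg/kg gives 0.488 mg/kg).

Note the sign flip between M2 and M4/M5: conditional on *total* Cd, higher pH
means less transfer (negative coefficient); conditional on a *bioavailable*
pool, which already absorbs most of the pH effect, the small residual pH
effect is positive. This is why thresholds derived from M2 rise with pH while
those from M4/M5 fall.

`fit_transfer()` re-estimates any such model by ordinary least squares on
$\log_{10} \mathrm{Cd}_{wheat}$. It refuses feature sets that mix two of the
three Cd pools (total, CaCl2, dissolved): they are so strongly correlated
that a joint fit is numerically fragile and scientifically uninterpretable.
Evaluation metrics (`evaluate_model()`) are computed on the log10 scale —
R² as the ordinary $1 - SSE/SST$ (reported unclamped, so a bad model can be
negative), RMSE and MAE on log10 residuals. The magnitudes of the published
fit metrics (RMSE around 0.2-0.3 for grain Cd averaging 0.3 mg/kg at R²
near 0.7) are only coherent on the log scale, which is why the package never
reports back-transformed errors.

## Threshold back-calculation and protection accuracy

`invert_threshold()` solves a model for its Cd variable at a grain limit
$L$ (default 0.1 mg/kg): for a log-linear model with Cd coefficient $b$,

$$\mathrm{threshold} = 10^{(\log_{10} L - \beta_0 - \text{other terms})/b},$$

and for M3, $L / \mathrm{BCF}(\mathrm{pH})$. The inversion is exact: a unit
test verifies `predict(model, invert(L)) == L` to 1e-9 relative and checks
the closed form against an independent log-scale bisection oracle.

`threshold_table()` reduces a continuous curve to one representative value
per pH band of the step standards. The representative pH is a parameter; the
default takes each band's lower boundary (5.5, 6.5, 7.5) and pH 4.0 for the
open acid band, the convention under which the package's M4 and M5 tables
agree with the published representative values at 3 decimals
(0.053/0.026/0.016/0.010 mg/kg and 0.009/0.005/0.003/0.002 mg/L). No single
convention we tested reproduces the published M3 row from the printed
3-decimal quadratic coefficients — it was most likely computed from
unrounded ones — and the published M2 row shows terminal-digit drift for any
single CEC value; neither row is therefore used as a check. When a curve
needs CEC (M2), the convention is to fix it at the mean CEC of the active
dataset; `threshold_curve(cec = NULL)` instead defers to each record's own
CEC during classification.

`classify_exceedance()` scores a rule against observed grain Cd: a record is
predicted-exceeding if its tested soil Cd pool is above the rule's threshold
at the record's pH, actually-exceeding if its grain Cd is above the limit.
Accuracy is $(TP + TN)/n \times 100$. Two built-in step standards are
provided: the agricultural-land standard (0.30/0.30/0.30/0.60 mg/kg by pH
band) and the stricter wheat-specific one (0.20/0.23/0.30/0.36 mg/kg), with
boundary pH values belonging to the lower band.

## The synthetic data generator

The 311-record field/literature dataset behind the published coefficients is
not deposited, so the package ships a generator (`generate_dataset()`)
whose defaults emulate that survey's published summary statistics. Design
choices, in order of how much they matter:

* **Marginals.** Each soil property is truncated-normal with bounds at the
  published range and the mean at the published value where one exists
  (pH 5.65) or the range midpoint otherwise. SDs are not published; they are
  set to range/5, so the printed extremes sit at about ±2.5 SD — wide enough
  to populate the whole range, narrow enough that the bounds are rare events.
  CEC has neither a published mean nor a symmetric-looking range; its mean
  (10.6 cmol/kg, a typical value for the rice-wheat rotation soils the survey
  covers) and the total-Cd log10-mean (-0.095, log10-SD 0.45, truncated to
  [0.068, 13.5] mg/kg) were calibrated once, by simulation over 200 seeds,
  so that a default dataset has arithmetic-mean total Cd near 1.329 mg/kg
  and mean BCF near 0.26.
* **Grain response.** $\log_{10}\mathrm{Cd}_{wheat}$ follows the M2
  equation plus Normal(0, 0.25) noise. The noise level brackets the
  published model quality: refitting M2 on a default dataset gives R²
  around 0.73 (tested to stay in [0.6, 0.85]).
* **Bioavailable pools.** Log-linear partition equations with signs
  (+ on log10 total Cd, − on pH, − on CEC), mirroring the published path
  structure (total Cd drives the bioavailable pool, pH and CEC suppress it,
  the pool drives grain Cd). The functional form is the package's own; the
  survey's path coefficients are used only as sign and rough-magnitude
  calibration. CaCl2 noise is 0.25 log10 units, set so that the physical
  clip (extractable ≤ total) fires in well under 1% of records.
* **Independence.** Properties are sampled independently apart from the
  explicit partition/response equations — no soil-property covariance matrix
  is published, and inventing one would only fabricate structure.

What passing tests on this generator do **not** show: performance on real
soils with correlated properties, literature/survey heterogeneity,
measurement error in the covariates, or spatial structure. The generator
makes the *procedures* testable (recovery, inversion, classification,
benchmarking), not the survey's dataset-bound numbers (its correlations,
R²/RMSE/MAE values, importance shares and accuracy percentages), which
cannot be reproduced without the original data.

Planted outliers (`n_outliers`) get grain Cd set to ten times the 3-SD BCF
bound of the clean sample, far enough out that the cleaning screen must
catch exactly them.

## Cleaning

`clean_dataset()` applies two one-pass rules: drop records missing a
required field (pH, CEC, total Cd, grain Cd), then drop records whose raw
BCF is outside mean ± 3 sample SD of the survivors. The screen uses the raw
(not log) BCF and does not recompute the SD after removals. A screened
dataset carries the screening record in its metadata and is not re-screened
— for heavy-tailed BCF distributions, an iterated empirical 3-SD screen
would keep shrinking the sample, so one-pass semantics and idempotence
require remembering that the screen has run.

## The benchmark harness

`run_benchmark()` reproduces the repeated-split protocol: each repeat draws
a 4:1 train/test split; hyperparameter grids with more than one point are
resolved by 10-fold cross-validation within the training set; the chosen
configuration is also refit on a 9:1 pre-train/validation sub-split (the
validation R² is recorded); the final model is fit on the full training set
and scored on the untouched test split. The label is always
$\log_{10}\mathrm{Cd}_{wheat}$; default features are the six soil properties
plus log10 total Cd. Eight learners are wrapped: ridge regression, a
decision tree, support-vector regression, k-nearest neighbours, random
forest, extremely randomized trees, and two gradient-boosting
configurations (a classic unregularised one — learning rate 0.1, depth 3,
no shrinkage penalties — and the regularised extreme-gradient-boosting
defaults), the latter two through the same boosting library since they are
the same algorithm family under different regularisation. Grids are small
and fixed on purpose: 100 trees for every ensemble (performance plateaus
there), tree depth in {unlimited, 10}, k in {3, 5, 7}, ridge penalty in
{0.1, 1, 10}. Desk-scale, reproducible tuning is the goal, not an
exhaustive search. Impurity-based importance shares (normalised to sum to
one) are collected for the tree ensembles.

Test-set leakage is auditable: the result object retains each repeat's
record identifiers, and a test asserts train/test disjointness per repeat.

## Numerical choices and degenerate inputs

* Truncated-normal sampling uses the inverse-CDF construction
  (`qnorm` of a uniform between the CDF bounds), exact and vectorised;
  `sd = 0` degenerates to the clamped mean.
* The BCF quadratic is fit by `lm` on `bcf ~ I(ph^2) + ph`; fewer than four
  distinct pH values is an error.
* `fit_transfer()` needs at least p+1 complete records (exact interpolation
  is allowed and reported as R² = 1); exact collinearity is an error, not a
  silent drop.
* Pearson p-values use the t approximation with pairwise-complete n;
  zero-variance variables yield flagged `NA`s rather than errors.
* Thresholds are kept at full precision; presentation rounding to 3
  decimals is a separate column in `threshold_table()`.
* Record identity is file-plus-row (or generator index); duplicate content
  is legal, duplicate identifiers are not.
* All randomness flows through explicit integer seeds; `generate_dataset()`
  and `split_dataset()` restore the caller's RNG state.

## Problem sizes used in the test suite

The suite fits models and runs the benchmark at n between 80 and 2000
records, 1-3 split repeats and 5-fold CV — sizes chosen so the full suite
documents the behaviour of every operation in well under a minute of CPU
while still giving the stochastic checks (coefficient coverage over 200
seeds, generator calibration over 50 seeds) enough replication to be
meaningful.

## Known limitations

* The generator emulates marginals and the path-sign structure, not the full
  joint distribution of real soils; cross-property correlations beyond the
  explicit equations are absent by design.
* The dissolved-Cd pool is an empirical log-linear proxy; no geochemical
  speciation model is computed.
* Thresholds carry no uncertainty bands; the source analysis publishes
  none, and bootstrap bands would suggest a precision the undeposited data
  cannot support.
* Literature screening and soil-database imputation used to assemble the
  original survey are documented here but intentionally not implemented.
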