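---
title: "Compositional analysis of diet and sleep: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of diet and sleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compsleep)
```

## The statistical model

Macronutrient intakes are treated as a 5-part composition of total energy:
gram intakes of protein, carbohydrate, saturated, monounsaturated and
polyunsaturated fat are multiplied by their calorie factors (4, 4, 9, 9,
9 kcal/g) and closed to sum to 1 (`energy_shares()`). A composition carries
only relative information, so analysis happens in log-ratio coordinates:

* `alr()` — additive log-ratios against the last part, used for exploratory
  transformation;
* `ilr()` — isometric log-ratios `z = B log(x)` under an orthonormal
  sequential-binary-partition basis (`make_basis()`). The *pivot* basis for
  a focal nutrient places that nutrient alone against the geometric mean of
  the rest in the first balance; positive `z1` means the focal share sits
  above the geometric mean of the others.

Each sleep outcome (total sleep time in hours, sleep-onset latency in
minutes, %WASO) is modelled by ordinary least squares on the four balance
coordinates plus age, sex (female = 1) and BMI, entered linearly and
uncentred — centring changes only the intercept and none of the reported
contrasts. The key estimands are *prediction differences*: the model's mean
prediction at a perturbed composition minus the prediction at the cohort's
compositional mean, with every covariate held at the same value in both
rows so it cancels exactly. Intervals use the residual standard error, the
model-matrix cross-product inverse and t critical values
(`predict_difference_ci()`); we use t quantiles, never the normal
approximation, and two-sided 95% intervals by default.

Two perturbations are supported at the compositional mean `x̄`:

* **proportional reallocation** (`reallocate()`): add δ of total energy to
  one nutrient and scale every other share by
  `(1 − x_f − δ)/(1 − x_f)` (take mode is the signed mirror). Only the
  focal nutrient's pivot balance moves — ratios among the other parts are
  untouched — which is what makes single-balance effect planting exact.
* **isotemporal substitution** (`substitute_pairwise()`): move δ from a
  donor to a recipient one-to-one, other parts byte-identical.

The default δ is 0.06 (6% of total energy). That value is the feasibility
cap implied by the smallest mean share — polyunsaturated fat sits near
6.5% of energy, and a take-6% reallocation must leave every share strictly
positive. `reallocate()` enforces the cap and raises an explicit error for
infeasible displacements; runtime feasibility is re-checked at the realized
compositional mean of each cohort.

Because mean predictions are invariant to the (orthonormal) basis used for
fitting, the pipeline fits **one** default-basis model per outcome and
forms all contrasts in that coordinate system; the tests assert bit-level
agreement with refitting under each focal pivot basis.

## Assumptions

* Linearity of outcomes in the balance coordinates (checked by the Ramsey
  RESET entry of `ols_diagnostics()`), homoscedastic errors
  (Breusch-Pagan), no residual autocorrelation (Durbin-Watson), and
  approximate residual normality (Shapiro-Wilk; with thousands of
  observations the t intervals are insensitive to moderate
  non-normality).
* Strictly positive compositions. Zero gram intakes in input data are
  replaced by 0.1 g (multiplicative-replacement convention) with a warning
  before closure.
* Cross-sectional, associational estimands: the reallocation and
  substitution differences are model predictions, not causal effects.

## The cohort filter

`apply_exclusions()` implements a three-stage cascade applied in a fixed
order: (1) drop rows missing any sleep summary; (2) drop rows whose TST
falls outside mean ± 3 sample SD, with the mean and SD computed **once** on
the post-stage-1 cohort (the SD is deliberately not recomputed after
removals); (3) drop rows with fewer than 7 retained days in *either* app
stream. Sample (n−1) SDs are used throughout. Day-level inputs are first
restricted to days with all three meals recorded
(`filter_complete_meal_days()`; a missing flag is indistinguishable from a
skipped meal) and to the overlap window of the two recording streams, then
averaged per participant (`restrict_overlap_and_average()`).

A note on idempotence: with unbounded (normal) TST, re-running the cascade
on its own output can trim the natural ~0.27% tail that the recomputed
±3 SD band exposes once planted outliers are gone. The second pass touches
at most the outlier stage; the cascade is a strict fixed point only when
the retained TST values lie inside the recomputed band.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces a cohort whose marginals match the study
conditions the package was built around:

| quantity | mean (SD) | distribution |
|---|---|---|
| TST | 6.7 (1.1) h | normal, redrawn into (0, 14] |
| SL | 21.5 (12.1) min | gamma (moment-matched), shifted, floored at 0 |
| %WASO | 9.9 (7.2) % | gamma, shifted, clamped to [0, 100] |
| age | 36.7 (10.4) y | normal, rejection-truncated to [18, 80] |
| BMI | 24.8 (4.8) kg/m² | normal, truncated to [14, 60] |
| female | 81.6% | Bernoulli |
| energy | 1662.6 (330.3) kcal | truncated normal |
| fiber | 11.7 (3.5) g/d | truncated normal |
| potassium | 2295.3 (602.1) mg/d | lognormal |
| Na/K ratio | 1.6 (0.4) | lognormal; sodium = ratio × potassium |

Gamma noise for SL and %WASO was chosen because a normal with these
moments would produce negative values; sodium is derived from the ratio so
the mean ratio is controlled exactly in expectation rather than emerging
from two independent marginals. Compositions are logistic-normal: four
default-basis balance coordinates drawn around `ilr` of the mean
composition (0.182, 0.538, 0.097, 0.118, 0.065) with diagonal SD 0.12 —
the simplest family that guarantees positivity and closure when only
marginal summaries are available. The mean composition is the *closed*
5-part vector; the corresponding published per-nutrient %kcal marginals
sum to 101.7% and are mutually inconsistent with closure (plausibly
because their denominators include alcohol energy), so the generator
targets the closed composition and not those rows.

Planted effects: each `planted_effect()` names a reallocation, an outcome
and a target difference. The generator places coefficients on the focal
pivot balances and solves the per-outcome linear system so that **every**
target holds exactly in the noiseless model, even when several effects
share an outcome and therefore contaminate each other's reallocation
geometry (`calibrate_balance_effect()` is the single-effect special case).
Planted terms and covariate terms (sex effects taken from the by-sex
marginal differences: +0.2 h TST, −2.4 min SL, −3.9 %WASO for female;
small age/BMI slopes) are centred at their sample means at generation
time, and the outcome noise variance is shrunk by the planted-term
variance, so configured marginal means and SDs are preserved.

What the generator does **not** emulate: day-of-week and seasonal intake
structure, correlation between energy intake and body size or sex,
measurement error of app-logged diets, within-person outcome
autocorrelation, or any nonlinearity of the diet–sleep relationship.
Passing recovery tests therefore show that the pipeline correctly inverts
the compositional model it assumes — not that real cohort estimates would
be unbiased under misspecification.

`generate_daily_logs()` adds multiplicative day-level noise (CV 0.15, a
typical day-to-day intake variation) over 28 days with an 80% chance that
a day records all three meals; it exists to exercise the filtering stage,
not to model diary behaviour. With nonzero `exclusion_counts` the cohort is
extended into a consented-roster fixture: rows with missing sleep
summaries, TST outliers planted at ±6 marginal SDs (far enough out to stay
outside the ±3 SD band even after the planted rows inflate the sample SD,
while remaining inside the (0, 14] plausibility range), and short-usage
rows with 1–6 recording days.

## Numerical choices

* `fit_ols()` solves via QR but retains the explicit `(X'X)^{-1}` (Cholesky
  of the cross-product) because the prediction-difference interval needs
  it; rank deficiency raises an error naming the collinear columns.
* Quartile cutpoints use the linear-interpolation percentile convention
  (`quantile` type 7) with right-closed intervals; labels would shift
  under other conventions, which is why the convention is fixed and
  documented.
* Log-ratio round-trips are exact to 1e-10; closure to 1e-9 is asserted on
  every operation returning a composition.
* Ties and degenerate inputs: quartile assignment requires ≥4 distinct
  values; `variation_matrix()` requires ≥2 samples; a single-row summary
  reports SD 0 by convention; diagnostics that cannot run at a given n are
  reported `NA`, never raised.
* No multiple-testing adjustment is applied anywhere; significance flags
  are simply "the 95% interval excludes 0".

## Problem sizes

The test suite validates properties at small-to-moderate sizes chosen for
sharpness per unit time: 1000 random compositions for round-trips, 100
random regression problems against an independent solver, 1000 simulated
datasets for interval coverage (95% ± 2%), cohorts of 150–2000 for
pipeline shape and invariance checks, and 20 independent full-size
(n = 4825) cohorts for planted-effect recovery, where the 95% intervals
must cover the planted truth in at least 80% of runs. The acceptance
script averages recovered estimates over 10 replicate full-size cohorts,
which reduces the Monte-Carlo standard error of the reported value about
three-fold relative to a single cohort.

## Known limitations

* The estimands inherit OLS assumptions; heavy heteroscedasticity or
  nonlinearity would bias intervals (the diagnostic battery is the guard).
* The 6% displacement is evaluated at the compositional mean only;
  person-specific reallocations away from their own composition are out of
  scope.
* The generator's covariate effects are fixed constants, not estimated
  from data; they exist so that adjustment has work to do, and their
  magnitudes should not be interpreted.
* Zero-intake replacement (0.1 g) is a convention; cohorts with many true
  zeros would need a principled zero-replacement model.
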