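---
title: "Compositional analysis of 24-hour movement behaviors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of 24-hour movement behaviors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movecoda)
```

## The problem

A child's day is exhaustively partitioned into four movement behaviors:
moderate-to-vigorous physical activity (MVPA), light physical activity
(LPA), inactivity, and sleep, together closing to 1440 min. Minutes spent
in one behavior can only come at the expense of another, so the four
columns carry purely *relative* information and are perfectly collinear by
construction. Regressing a cognitive outcome on raw minutes is therefore
ill-posed, and coefficients on single behaviors are uninterpretable.
`movecoda` implements the standard compositional-data answer: analyze the
composition in isometric log-ratio (ilr) coordinates, interpret one
behavior at a time by rotating the coordinate system, and translate fitted
models into *isotemporal substitution* estimates — the predicted outcome
change when a fixed number of minutes is moved between two behaviors.

## Coordinates: sequential binary partition and rotations

For the ordered parts $(x_1, \dots, x_D)$ the pivot (sequential binary
partition) coordinates are

$$\mathrm{ilr}_k = \sqrt{\frac{D-k}{D-k+1}}\,
  \ln\frac{x_k}{\left(\prod_{j>k} x_j\right)^{1/(D-k)}},
  \qquad k = 1, \dots, D-1 .$$

With the behavior order (MVPA, LPA, inactivity, sleep),
$\mathrm{ilr}_1 = \sqrt{3/4}\,\ln\big(\mathrm{MVPA} /
\sqrt[3]{\mathrm{LPA}\cdot\mathrm{Inactivity}\cdot\mathrm{Sleep}}\big)$:
the relative share of MVPA against everything else. The contrast matrix has
orthonormal, sum-zero rows, so the coordinates are an isometry of the
Aitchison geometry; `ilr_transform()` / `ilr_inverse()` round-trip to
better than $10^{-10}$ and are invariant to rescaling of the input
(minutes and proportions give the same coordinates).

Only the first coordinate is interpreted. To read off every behavior,
`rotate_basis()` (or `lead=` in `coda_lm()`) cycles the part order so each
behavior in turn leads the partition. All four rotations span the same
$(D-1)$-dimensional subspace, which yields three exact consequences used
throughout the tests:

* fitted values, residuals, $R^2$ and the joint composition test of a
  regression are identical across rotations;
* the lead-$k$ first coordinate equals $\sqrt{D/(D-1)}$ times the $k$-th
  centered log-ratio (clr) component, so the four rotation-wise ilr1
  coefficients, scaled by $\sqrt{(D-1)/D}$, are the model's clr
  coefficients and sum to zero exactly;
* Aitchison distances computed in any rotation's coordinates agree.

The residual (non-lead) part order is kept cyclic. It affects the numeric
values of $\mathrm{ilr}_2, \mathrm{ilr}_3$ but not fitted values,
predictions, or any reported quantity; the choice is cosmetic and fixed
for reproducibility.

## Regression and the per-behavior table

`coda_lm(outcome ~ covariates, data, parts = ...)` adds the three ilr
coordinates to the design and fits ordinary least squares. The unadjusted
model is `outcome ~ 1`; the adjusted model adds sex, ethnicity, maternal
age, maternal education, and child BMI. Missing data are handled by
listwise deletion, so each model reports its own analysis n.
`rotation_table()` refits under the four leads and reports, per behavior,
the ilr1 estimate with a normal-theory Wald 95% CI and p-value, plus a
joint composition p-value: a partial F-test (3 numerator df) of the ilr
block against the covariate-only model. The block test is not sensitive to
the rotation.

Two conventions are decided here because the convention is genuinely open:

* **Maternal age** enters as a 3-band categorical variable (<27, 27–33,
  >33 years), matching how cohort descriptives are usually tabulated; a
  continuous coding would be equally defensible.
* **Joint test form**: partial F rather than a likelihood-ratio test; for
  Gaussian OLS the two are monotone transformations of each other and
  numerically near-identical at these sample sizes.

## Isotemporal substitution

`reallocate()` moves $t$ minutes from a donor to a recipient behavior at a
reference composition (all other parts untouched). `predict_difference()`
evaluates the fitted model at the perturbed and reference compositions;
covariate terms cancel, leaving
$\Delta = \beta^\top\{\mathrm{ilr}(x_{new}) - \mathrm{ilr}(x_{ref})\}$.
Because $\Delta$ is linear in the coefficients, the delta-method interval
from the coefficient covariance is exact given the model, and it is the
default; a nonparametric bootstrap (resampling children, refitting) is
available via `method = "bootstrap"` for users who prefer not to lean on
normal theory. The reference composition defaults to the closed geometric
(compositional) mean of the analysis sample, the natural center of the
Aitchison geometry; an arithmetic-mean reference is available behind
`reference = "arithmetic"` for comparison.

`substitution_surface()` evaluates all 12 ordered behavior pairs over a
5–60 min grid (5-min steps). Reallocations are *not* antisymmetric: moving
30 min out of a 68-min MVPA mean is a much larger log-ratio perturbation
than moving 30 min out of a 542-min sleep mean, so forward and reverse
estimates differ in magnitude — they agree (with opposite sign) only in
the small-duration limit, which is tested as a Taylor-limit property.
Durations that meet or exceed the donor's reference minutes are flagged
infeasible rather than dropped.

`reconstruct_clr_coefficients()` inverts the rotation identity: given the
four published rotation-wise ilr1 estimates, $\gamma_k = \sqrt{3}/2\,b_k$,
re-centered to sum to zero to absorb 3-decimal rounding of the inputs.
This recovers the substitution machinery of a published model without any
access to the underlying data, and is how the package's worked example
(`worked_example()`) reproduces published 30-min MVPA/sleep reallocation
estimates to within ±0.01.

```{r worked}
worked_example()
```

## Latent cognitive scores

Executive function is scored from inhibition errors, switching errors
(both error counts: higher is worse) and working memory; academic
achievement from spelling, oral reading rate, oral reading accuracy and
numerical operations. `latent_score()` z-scores the indicators, flips the
error-count columns so the latent reads "higher is better", and fits a
one-factor maximum-likelihood model with regression-method factor scores —
the common default where a report says only "factor analysis". Scores have
mean 0 and SD below 1 (regression-score shrinkage; e.g. three indicators
loading 0.7 give score SD near 0.86). If the ML solution is a Heywood case
or fails to converge, the function warns and falls back to the first
principal component of the z-scored indicators, standardized to unit
variance. The orientation and method are recorded in the returned object.

## Domain-specific activity models

Parent-reported activities are preprocessed by fixed convention:
organized PA/sports, active commuting and board/card games are
dichotomized at strictly positive minutes (`dichotomize()`; participation
questions behind such items are not always available, so >0 is the
operational rule and it is documented in the output); indoor and outdoor
active play are cut at the analysis sample's tertiles
(`tertile_categorize()`, boundary ties to the lower category for
determinism; a warning reports ties when more than a third of values
coincide); screen and reading times enter continuously in h/day.

`domain_lm()` fits one exposure at a time. Model 1 is the exposure alone.
Model 2 adds the demographic covariates and the exposure's block:
PA exposures are co-adjusted for the other PA domain variables plus
accelerometer-measured inactivity and total sleep; SB exposures for the
remaining SB variables plus accelerometer-measured MVPA and total sleep.
Accelerometer minutes enter these models as raw min/day covariates, not as
ilr coordinates — here they are confounders, not the exposure of interest.
Total screen-viewing time is the exact sum of its four components, so SVT
and TV/handheld can never share a design; the function enforces this.
Tertile exposures report medium-vs-low and high-vs-low contrasts plus a
2-df partial-F joint p.

## The synthetic cohort generator

No public data accompany the motivating design, so validation rests on a
generator (`simulate_cohort()`) that emulates the cohort's *structure*:

* **Behavior law.** Daily minutes follow a logistic-normal law: Gaussian
  child-level effects plus independent day-level noise on the log-part
  scale (equivalently, Gaussian in ilr coordinates), a weekend shift on
  the log scale, and closure of each day to 1440 min. The logistic-normal
  choice guarantees positivity and closure and makes planted ilr-scale
  effects exact. One refinement was forced by the geometry: with fully
  independent log parts, closure leaks the large inactivity/LPA variance
  into sleep and the closed sleep SD cannot get down to realistic values,
  so the child-level law includes a positive inactivity–sleep log
  correlation (0.51 at age 5.5, 0.30 at age 8) — the compensation between
  waking inactivity and sleep seen in real time use.
* **Calibration.** Child-level log-means and log-SDs were calibrated once
  by moment-matching simulation so that the *weighted-week* minutes match
  the target arithmetic means and SDs (72/347/487/535, SD 24/48/67/42
  min/day at age 5.5; 72/335/510/523, SD 26/54/68/45 at age 8), and then
  frozen as package defaults. Day-level log-SDs (0.35/0.18/0.15/0.10) and
  the weekend shift are not identified by any published table; they were
  chosen once as realistic for wrist-accelerometer time use in children
  and are exposed in the config. The within-child weekday/weekend
  correlation is governed by the child/day variance split rather than a
  separate knob.
* **Validity and weighting.** Wear-time compliance is emulated as a
  Bernoulli valid/invalid flag per day (default 0.85); the underlying
  16 h/day wear rule is represented by this flag, not recomputed from
  epochs. A child's timepoint is retained with at least two valid weekdays
  and one valid weekend day, and retained days are combined with 5:2
  weekday:weekend weighting, then closed. Total sleep is generated
  directly as a single part — in the emulated protocol it corresponds to
  night sleep plus daytime naps (sustained inactivity of at least 15 min
  outside the night window); nap detection itself is signal processing and
  out of scope.
* **Timepoint missingness** is a per-timepoint measurement probability
  (defaults 0.73 at age 5.5, 0.90 at age 8), reproducing differing
  per-model sample sizes and giving the complete-case sensitivity subset
  something to do.
* **Domain variables and covariates** are Bernoulli participation flags
  and log-normal durations with weekday/weekend structure, calibrated to
  the target prevalences (organized PA 45%, commuting 58%/52%, board
  games 33%/35%) and means; covariates follow the published marginal
  distributions, with BMI correlated 0.7 across ages.
* **Outcomes.** A latent outcome is a linear predictor on the MVPA-first
  ilr coordinates of the weighted-week composition plus named
  domain/covariate terms plus Gaussian noise (`noise_sd`); indicators load
  on the standardized latent with unit-variance residual split and are
  then placed on plausible raw scales. All planted effects default to
  zero.

**What passing tests do and do not show.** The generator reproduces
marginal means/SDs, prevalences, closure, the validity/weighting
mechanics, and a known linear outcome model. It does not emulate
epoch-level wear, posture, seasonality, informative (non-random)
missingness, measurement error in parent reports, or non-linear
dose–response. Parameter-recovery results therefore validate the
estimation machinery under the stated model, not the substantive
conclusions one would draw from real cohort data.

## Numerical choices and degenerate inputs

* Closure conserves totals to 1e-9 relative; ilr round-trips are tested at
  1e-10; rotation invariance of fitted values at 1e-8 (accumulated
  refitting error), of substitution deltas at 1e-10.
* Exact zero minutes (possible in parent-reported or coarsely processed
  inputs) are repaired by multiplicative replacement with a configurable
  1-min floor: zeros become the floor and the remaining parts shrink
  proportionally, preserving their ratios and the total. The log-ratio
  transforms refuse non-positive parts and point to `zero_replace()`.
* Degenerate tertiles (a boundary undefined because more than a third of
  values tie) warn and collapse the affected category rather than failing.
* Collinear designs are an error naming the aliased columns, not a silent
  NA coefficient.

## Validation scale

The simulation-based checks use sizes chosen to make Monte-Carlo error
small relative to the assertion bands: 1,000 replicates at n = 300 for
CI coverage (expected in [93%, 97%]) and joint-test type-I error
([3.5%, 6.5%] at $\alpha = 0.05$); 400 replicates for p-value uniformity
under the null; n = 2,000 for generator calibration (3 Monte-Carlo SEs).
Coverage is assessed on the generator's latent outcome rather than the
factor-scored outcome, since score shrinkage attenuates coefficients by
construction — that attenuation is a property of factor scoring, not an
estimation defect, and is documented above.

## Known limitations

* Two timepoints are modelled separately, as in the motivating design; no
  joint longitudinal model.
* Standard errors are classical OLS (no robust/clustered variants).
* Substitution is evaluated at the sample compositional mean, not at
  per-child compositions.
* The ilr construction is limited to sequential binary partitions (pivot
  balances); general balance trees with multi-part numerators are out of
  scope.
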