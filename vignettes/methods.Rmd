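---
title: "Parent-offspring body-composition transmission: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-offspring body-composition transmission: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triocomp)
```

## The scientific question

How strongly does each parent's body mass index (BMI) predict a child's
body composition, and does the answer differ for fat mass versus lean
mass, for mothers versus fathers, and for sons versus daughters? Answering
this requires more than BMI on both sides: offspring BMI mixes fat and
lean tissue, so the package works with the four-component (4C) model of
body composition, which partitions weight using body volume (air
displacement plethysmography), total body water (deuterium dilution) and
bone mineral content (DXA):

$$FM = 2.747\,BV - 0.710\,TBW + 1.460\,BMC - 2.050\,W, \qquad LM = W - FM.$$

Dividing by squared height gives the fat mass index (FMI) and lean mass
index (LMI), which by construction sum to BMI. Offspring indices are
standardised to age- and sex-specific z-scores by the LMS method,

$$z = \frac{(x/M)^L - 1}{L\,S}, \qquad z = \frac{\ln(x/M)}{S} \ \text{as}\ L \to 0,$$

where the log-limit branch is taken for $|L| < 10^{-7}$. The analysis then
regresses each offspring z-score on parental BMI, with the other parent's
BMI included to account for assortative mating, multiple imputation for
missing paternal anthropometry, and a sensitivity analysis for
non-paternity.

## Why a synthetic cohort

No individual-level data are distributed with the cohort this package
emulates, and the British 1990 / UK body-composition LMS reference tables
are licensed and cannot be redistributed. The package therefore ships two
synthetic components, both first-class, tested code:

* `synthetic_lms_reference()` builds smooth LMS tables (ages 5-22, both
  sexes, BMI/FMI/LMI) in the same CSV schema as real references. BMI uses
  a mild negative Box-Cox power (L = -0.5), FMI and LMI are lognormal
  (L = 0) with girls' FMI medians above boys'; LMI medians are the BMI
  minus FMI medians so realised values centre near the reference median.
  Real tables in the same schema (`measure, sex, age_y, L, M, S`) can be
  dropped in wherever a reference is accepted.
* `simulate_trios()` generates the cohort itself.

## What the generator emulates

`trio_config()` holds every distributional choice; its defaults are the
study conditions the package is calibrated to:

* **Parental BMI.** Bivariate normal, maternal mean 25.4 (SD 5.0),
  paternal mean 26.4 (SD 3.9) kg/m^2, truncated to [16, 44] kg/m^2 (the
  plausible observed range) by joint resampling. Truncation shrinks the
  realised correlation by a closed-form factor of about 0.914, so the
  latent correlation defaults to 0.1565, making the realised
  mother-father correlation 0.143 — the assortative-mating strength the
  analysis is calibrated to (and the value at which the two-predictor
  variance inflation factor is 1/(1-r^2) = 1.021). Truncation also shifts
  the realised maternal mean slightly above the latent 25.4; descriptive
  checks compare against the truncated-normal closed form.
* **Transmission.** $z = \beta_m (M - \mu_m) + \beta_f (B - \mu_f) +
  \varepsilon$ per outcome, with sex-specific defaults equal to the
  adjusted coefficients the cohort reported (for BMI z: 0.074/0.057 in
  boys, 0.071/0.029 in girls per kg/m^2, maternal/paternal; analogous
  values for FMI and LMI). $B$ is the *biological* father's BMI. With
  sex-specific coefficients the all-offspring regression targets the
  sex-ratio-weighted mixture (about 0.0725 maternal, 0.0426 paternal for
  BMI z at the default 0.485 male fraction), which is what
  `implied_marginal_beta()` returns and what parameter-recovery tests
  compare against.
* **Residual scale and cross-outcome dependence.** The cohort reports no
  residual variances; residual SDs default to 1.07/0.95/1.04 so that
  total z-score SDs come out near the reported 1.0-1.16. Residuals are
  correlated across outcomes (0.85 BMI-FMI, 0.50 BMI-LMI, 0 FMI-LMI):
  within a subject the three indices are mechanically linked, and without
  this dependence the lean-mass index implied by weight minus fat mass
  would be far more dispersed than any real reference allows.
* **Raw measurements.** Only two of the three z-scores can be prescribed
  freely because FMI + LMI = BMI in raw units. Following the inverse
  construction, weight is the inverse-LMS of the drawn BMI z-score times
  height squared, fat mass the inverse-LMS of the drawn FMI z-score,
  lean mass the complement; TBW = 0.73 LM (lean-tissue hydration),
  BMC = 0.04 W, and body volume is solved from the 4C equation so the
  pipeline recovers fat mass exactly. The realised LMI z-score is
  therefore *implied*; the truth table records it as `lmi_z_implied`
  alongside the drawn value, and round-trip tests assert exactness for
  BMI/FMI and consistency for LMI. Draws whose inverse-LMS leaves the
  Box-Cox domain (or would imply non-positive lean mass) have their
  residuals redrawn with bounded retries — a sub-0.1% truncation at the
  defaults.
* **Heights.** Offspring height follows a quadratic age/sex mean curve
  (SD 7 cm); parental heights are normal (mothers 163.5 (6.3) cm, fathers
  177.0 (6.7) cm), and parental weights are derived from BMI and height.
* **Missingness and non-paternity.** Paternal weight and height are
  masked jointly, missing completely at random, at 14% by default.
  Non-paternity defaults to 0: it is a sensitivity scenario, not part of
  the observed-data model. `apply_nonpaternity(p)` replaces each reported
  father with probability p by a fresh draw from the conditional
  distribution of a partner's BMI given the mother's (preserving the
  mother/reported-father covariance — the equal-correlation convention),
  while offspring z-scores stay tied to the biological father.

What the generator does **not** emulate: instrument measurement error of
the 4C inputs, non-MCAR missingness, secular/cohort effects, and any
nonlinearity of transmission. Passing parameter-recovery tests therefore
demonstrates correctness of the estimation machinery under the assumed
data-generating model, not robustness to violations of it.

## Imputation

Missing paternal weight and height are imputed by chained equations with
Bayesian normal-linear draws: the residual variance is drawn from its
scaled inverse-chi-square posterior, coefficients from their normal
posterior, and imputations from the posterior predictive. Predictors are
the mother's BMI, the three offspring z-scores, offspring age and sex,
plus the other paternal variable through the chaining; 10 burn-in cycles;
per-cycle means of the imputed values are logged for convergence
inspection. Father BMI is derived from imputed weight and height, keeping
completed tables in the raw CSV schema. Estimates are pooled by Rubin's
rules with Barnard-Rubin small-sample degrees of freedom (the classical
large-sample formula is the dfcom = Inf limit). The imputation model is
recorded in a JSON sidecar by the analysis scripts, since the original
analysis does not state its exact predictor set.

## Regression

`fit_model()` is ordinary least squares with an intercept; coefficients
are per one kg/m^2 of parental BMI (never standardised — rescaling would
silently change the meaning of the coefficients). Adjusted models include
both parents' BMI; strata are refit per subset rather than via
interaction terms, matching how the association table is presented.
Confidence intervals use the t distribution with residual degrees of
freedom; heteroscedasticity-robust (HC3) errors are available behind a
flag but off by default. `fit_grid()` enumerates all 36 cells (3 outcomes
x 2 exposures x unadjusted/adjusted x 3 strata) and Rubin-pools each cell
across completed tables when given an imputation set.

## Non-paternity correction

If a fraction $p$ of reported fathers are not biological, the fitted
paternal coefficient is attenuated and, through assortative mating, part
of the paternal signal contaminates the maternal coefficient. With
$\sigma_{mm}$, $\sigma_{ff}$ the maternal and reported-paternal BMI
variances, $\sigma_{fm}$ their covariance, and the mother/biological-
father covariance $\sigma_{bm}$ expressed through the indicator weight
$a$ ($a = 1 \Leftrightarrow \sigma_{bm} = \sigma_{fm}$, the
equal-correlation convention used by default; $a = 1-p \Leftrightarrow
\sigma_{bm} = 0$), the reported/biological-father covariance is

$$\sigma_{fb} = (1-p)\,\sigma_{ff} + p\,\sigma_{fm}\sigma_{bm}/\sigma_{mm},$$

and the corrected coefficients are $\beta^* = \Lambda \hat\beta$ with
$\Lambda = A^{-1}\Sigma$, $A = \begin{pmatrix} \sigma_{mm} & \sigma_{bm}
\\ \sigma_{fm} & \sigma_{fb} \end{pmatrix}$ and $\Sigma$ the observed
parental covariance matrix. $\Lambda$ is upper-triangular with unit
leading entry; for $a = 1$ it reduces to

$$\beta_1^* = \hat\beta_1 - \frac{p}{1-p}\,\hat\beta_2\,
\frac{\sigma_{fm}}{\sigma_{mm}}, \qquad
\beta_2^* = \frac{\hat\beta_2}{1-p}.$$

The printed source of this correction is typographically unreliable, so
correctness rests on properties rather than transcription:
`adjust_coefficients()` evaluates the closed-form expressions *and* the
numeric matrix solve and insists they agree to 1e-10; the correction is
the exact identity at p = 0; it is monotone (maternal non-increasing,
paternal non-decreasing in p) on calibrated fits; and slopes estimated on
synthetic data carrying true non-paternity p, corrected at that same p,
recover the generating coefficients — the whole chain, generator included,
is internally consistent. The derivation is exact for the generator's
replacement model; under a different replacement mechanism the
through-mother term in $\sigma_{fb}$ (order $p\,\rho^2$, well under 1% of
$\sigma_{ff}$ here) would change slightly.

The default p grid {0, 0.01, 0.02, 0.05, 0.10, 0.15, 0.20} spans
conventional non-paternity estimates; p is always an assumed scenario,
never estimated from data.

## Bootstrap difference test

The hypothesis "maternal effect larger than paternal" is tested by
resampling trios with replacement; each replicate re-imputes (m = 2 by
default — pooled *point* estimates drive the statistic, so small m trades
negligible precision for tractability; the main-analysis m = 10 remains
available via the `m` argument), refits the adjusted model, corrects at
the assumed p, and records $d = \beta_1^* - \beta_2^*$. The one-sided
p-value is $(\#\{d \le 0\} + 1)/(B + 1)$. Resampling is unstratified by
offspring sex (the original analysis does not say; the outcome model is
sex-blind at the all-offspring level where the test is applied).
Replicates with degenerate designs are dropped and counted, with more
than 5% drops an error. B defaults to 10,000 for final runs; the test
suite and example scripts use B in the hundreds, with correspondingly
widened Monte-Carlo tolerances.

## Numerical choices and degenerate inputs

* The 4C equation may produce fat mass below zero or above weight on
  noisy inputs; values are flagged with a warning and propagated, never
  clamped, since clamping would bias downstream regressions.
* LMS reference interpolation is linear in age, component-wise on
  (L, M, S), with no extrapolation; the exact interpolation rule of the
  original spreadsheet tooling is unknown, and linearity on a 0.5-year
  grid is well within the tolerance of everything downstream. An optional
  `cap_age` flag evaluates ages beyond the oldest reference band at that
  band (the "use the 20-year reference for 21-year-olds" convention); it
  is off by default.
* Quintile boundaries in the descriptives table use linear interpolation
  of order statistics (`quantile` type 7), stated in the report footer.
* Zero residual variance, zero missingness and p = 0 are all valid
  degenerate configurations and are exercised by tests (the CI collapses
  onto the point estimate when the residual SD is 0).
* All randomness flows from explicit integer seeds; a configuration fully
  determines every CSV byte the pipeline writes.

## Problem sizes

Defaults mirror the emulated study (n = 511, m = 10, B = 10,000).
Test-suite and example runs use the sizes at which Monte-Carlo error, not
runtime, is the binding constraint: n = 50,000 for moment recovery,
n = 20,000 for transmission recovery through imputation, 200 runs of
B = 199 for bootstrap size calibration, n in the hundreds for smoke
tests. The methods are identical at all sizes.

## Known limitations

* The three z-scores cannot all be prescribed independently; the
  generator's LMI transmission coefficients govern the drawn truth values
  used in regression-recovery tests, while pipeline LMI estimates reflect
  the implied (additivity-constrained) z-score.
* Imputing father weight and height separately and deriving BMI is mildly
  uncongenial with a linear-in-BMI outcome model; at 14% missingness the
  effect is well below the tolerances used anywhere.
* The synthetic LMS reference is plausible, not real; absolute z-scores
  from real cohorts require the licensed reference tables.
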