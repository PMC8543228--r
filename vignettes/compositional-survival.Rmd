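---
title: "Compositional survival analysis of daily movement behaviours: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional survival analysis of daily movement behaviours: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codasurv)
```

## The problem

A day holds a fixed 1440 minutes.  Time spent asleep, sedentary (SB), in
light physical activity (LIPA) and in moderate-to-vigorous physical
activity (MVPA) therefore carries only *relative* information: increasing
one behaviour necessarily displaces the others.  Treating the four
durations as independent covariates in a mortality model ignores this
codependence and produces coefficients with no coherent interpretation.
`codasurv` analyses the daily time-use pattern as a *composition* and
asks how the balance between behaviours relates to the hazard of death.

## Balance coordinates

A composition with parts (Sleep, MVPA, LIPA, SB) is mapped to three
isometric log-ratio (ilr) balances:

* `z1` — sleep against the geometric mean of the waking behaviours,
  `sqrt(3/4) * ln(Sleep / (MVPA * LIPA * SB)^(1/3))`;
* `z2` — MVPA against the geometric mean of LIPA and SB,
  `sqrt(2/3) * ln(MVPA / sqrt(LIPA * SB))`;
* `z3` — LIPA against SB, `sqrt(1/2) * ln(LIPA / SB)`.

The contrast matrix is orthonormal, so the coordinates are an isometry of
the simplex: scale-invariant (minutes, hours and proportions give the
same `z`), and *subcompositionally consistent* — `z2` and `z3` computed
from the waking-day 3-part subcomposition equal those from the full day.
Both properties are tested numerically.  This particular nesting is
deliberate: it confines sleep to a single coordinate, which is what makes
it possible to pool studies that never measured sleep (below).  Other
orthonormal bases would give the same fitted model in different
coordinates; the package hard-codes this one and does not expose basis
sweeps.

## Rounded zeros

Devices scored in 1-minute epochs cannot record MVPA below one minute;
such days appear as zeros, which log-ratios cannot accept.
`impute_zeros()` treats zeros as left-censored at a per-part detection
limit (default 1 min/day, configurable per study) and imputes them with
an EM algorithm on additive log-ratios against a zero-free reference
part: the E-step fills each censored cell with the conditional mean of
the truncated normal implied by the current mean and covariance, the
M-step re-estimates both.  Initialisation is multiplicative simple
replacement at 65% of the limit; iteration stops when no imputed
log-ratio moves by more than 1e-4 (at most 50 iterations).  Imputed
values are strictly positive and strictly below the limit; rows without
zeros pass through untouched apart from closure, and the observed parts
of an imputed row keep their mutual ratios exactly because the row is
re-closed to its original total.  Imputation happens before closure
re-scaling, and a part that is zero everywhere aborts: no information
exists to impute it.

## The per-study model

Each study fits a Cox proportional-hazards model whose linear predictor
is `gamma' z + beta' v` — the ilr balances plus whatever covariates the
study's protocol specifies (covariate lists are schema-driven from the
cohort file, not hard-coded).  Fitting delegates to
`survival::coxph()` with the Efron tie approximation (follow-up times
rounded to coarse units make ties common enough to matter) and a
relative partial-likelihood convergence tolerance of 1e-9.

To limit reverse causation (illness reducing activity *and* causing
death), deaths in the first two years of follow-up are removed before
fitting (`landmark_filter()`).  Subjects *censored* before the landmark
are retained — the exclusion targets early deaths, not early exits — and
a flag switches to dropping all short follow-up if a user prefers the
stricter convention.  Follow-up clocks are not reset; the landmark is a
filter, not a left-truncation, which matches treating the model's time
origin as the accelerometer wear date.

Proportional hazards are checked per study with the scaled-Schoenfeld
score test (`survival::cox.zph`, KM time transform) plus a Kaplan-Meier
inspection helper (`km_by_risk_group()`); the package validates by
simulation that the global test holds its nominal size under a correctly
specified model and detects a sign-switching effect with high power.

## Federated pooling

Studies never share subject-level data: each exports coefficients, their
covariance and sample sizes as a JSON exchange file (numbers travel as
decimal strings with 17 significant digits, so a write/read round trip is
value-exact).  Pooling combines study coefficient vectors under a
multivariate random-effects model, `theta_i ~ N(mu, S_i + Psi)`, with
the between-study covariance `Psi` estimated by REML (direct
maximisation over a log-Cholesky parameterisation, which enforces
positive semi-definiteness by construction); the pooled estimate is the
inverse-variance weighted combination with weights `(S_i + Psi)^-1`.
The univariate reduction of this REML estimator agrees with `metafor` to
numerical precision, which the test suite uses as an independent
cross-check.

Studies that observe only the waking day contribute no information on
the sleep balance.  Because the basis confines sleep to `z1`, such a
study is lifted onto the 3-coordinate system by setting its `z1`
coefficient to zero with an arbitrarily large variance (default 1e6;
any value above 1e4 is indistinguishable) and zero cross-covariance.
Its weight on `z1` is then negligible while its `z2`/`z3` information is
kept in full.

A methods note on the moments fallback (`method = "mm"`): it is
implemented as *per-coordinate univariate DerSimonian-Laird*, not as a
diagonal-`Psi` multivariate fit.  With full multivariate weighting the
coordinates couple through the within-study covariances, so adding any
study — masked or not — legitimately moves every pooled coordinate via
the re-estimated `Psi` and weights; the "masked studies shift pooled
`z1` by less than 1e-3" guarantee is exact only when coordinates
decouple, and that is the estimator under which the package asserts it.
Under REML the package instead guarantees insensitivity to the mask
variance itself (1e6 vs 1e8 changes pooled `z1` by < 1e-4).

Heterogeneity is summarised per coordinate by Cochran's Q with
fixed-effect weights, its chi-square p-value and
`I2 = max(0, (Q - df)/Q)`; masked coordinates are excluded from their
coordinate's statistic.  `leave_one_out()` repeats the pooling dropping
one study at a time and per device stratum (wrist/hip), the sensitivity
analysis that matters most here because wrist- and hip-worn devices
classify behaviour differently enough to warrant stratified reporting.

## Effect estimation

All downstream quantities derive from one identity: between two
compositions the log hazard ratio is linear in the difference of their
ilr coordinates, `log HR = gamma' (z_a - z_b)`.  Confidence intervals
are Wald intervals on the log scale with variance
`dz' V dz`, treating the compositions as fixed — exact, not a delta
approximation, because the log-HR is exactly linear in the coefficients.

* `unit_hazard_ratios()` — `exp(gamma_j)` per one-unit balance increase.
* `select_reference()` — fits a bivariate normal to observed
  `(z2, z3)`, and returns the inverse-ilr of
  `mu + r * Sigma^(1/2) u`, with `r^2` the chi-square(2) quantile at the
  chosen coverage (default 0.75).  The point sits exactly on the
  constant-Mahalanobis contour: a deliberately unfavourable but
  data-supported reference.  The direction `u` is standardised
  (applied after `Sigma^(1/2)`) and configurable; the default
  `(-1, -1)` targets low MVPA and a low LIPA:SB balance, one reading of
  "low activity"; other readings are a one-argument change.
* `dose_response()` — varies one behaviour over a grid, the others
  keeping their reference ratios (or SB fixed with LIPA absorbing the
  remainder), and returns HR with CI per grid value; infeasible points
  are dropped with a warning.
* `joint_heatmap()` — the MVPA-by-SB surface with LIPA as the waking
  remainder (defaults: MVPA 0-120 by 1, SB 420-900 by 5 min, waking
  total 960 min = 16 h, i.e. 8 h sleep as in the figure conventions it
  mirrors; zero-MVPA grid points are clamped to 0.5 min to stay inside
  the simplex).  Cells with non-positive implied LIPA are masked.
* `solve_reallocation()` — the inverse problem: how many minutes must
  move out of SB into MVPA (LIPA fixed) or into LIPA (MVPA fixed) to
  reach a target hazard ratio.  The HR is monotone along the
  reallocation path, so a bracketed root search on (0, SB - 1 min)
  suffices; the root is solved to an HR tolerance of 1e-6 and reported
  rounded to the nearest minute alongside the exact value.  CI bounds
  solve the same equation on the Wald bound curves, which is what
  produces the strongly asymmetric intervals typical of these tables; a
  target the bound curve never reaches yields an infinite bound, and an
  unreachable point target returns the attained infimum rather than an
  answer.

The bundled `published_pooled_model()` coefficient sets carry only point
estimates and marginal 95% bounds, so their covariance is diagonal:
HR point estimates computed from them are exact, interval widths ignore
the (unpublished) between-coordinate correlation.  Intervals that
depend on that correlation — notably the upper bounds of the
substitution-minute solutions — are therefore wider than those computed
from a full covariance.

## The synthetic cohort generator

Because the real cohorts are access-restricted, the package validates
itself on synthetic data whose structure matches what the analysis
assumes:

* **Compositions** are logistic-normal — multivariate normal in ilr
  space, inverse-transformed and closed.  This is the same family the
  reference-selection step fits, so it is the natural generative
  counterpart.  Defaults: a waking-day centre of (MVPA, LIPA, SB) =
  (8, 350, 600) min — a realistic low-activity adult day — with ilr
  standard deviations (0.8, 0.4) and correlation 0.2; the 24-h variant
  centres at (Sleep, MVPA, LIPA, SB) = (440, 30, 250, 720) with sd
  (0.15, 0.8, 0.4) for (z1, z2, z3).
* **Event times** follow the proportional-hazards model exactly, with an
  exponential (default) or Weibull baseline inverted analytically.
  Default coefficients use the magnitudes of the published
  device-stratified estimates, and the default baseline rate
  (0.0019/year over an 8-year horizon with a 2-year uniform entry
  window) was calibrated once so that the default event fraction is
  about 3%, the pooled mortality fraction of the motivating consortium.
  Recovery experiments use higher rates (stated in each script/test) so
  that coefficient estimates are informative at desk-scale n.
* **Rounded zeros** arise mechanistically: a subject whose drawn MVPA
  falls below the 1-min detection limit is recorded as zero with
  probability `zero_p` (default 1).  At the default centre about 2% of
  subjects sit below the limit, matching the study condition the
  imputation step is designed for, and the sub-limit truth is exactly
  the logistic-normal tail that the log-ratio EM models.
* **Determinism**: each subject consumes a fixed block of eight
  uniforms from one seeded stream, so the same seed reproduces a cohort
  byte-for-byte and the first n subjects are unchanged when n grows.

What the generator does *not* emulate: accelerometer measurement error
and device-placement misclassification (the very thing that makes wrist
and hip studies disagree), covariate-composition confounding beyond the
two built-in covariates, non-proportional hazards, competing risks, and
informative censoring.  Passing recovery tests therefore demonstrate
that the pipeline estimates what it claims *when its model holds*; they
say nothing about robustness to measurement differences between devices,
which is precisely why device-stratified pooling and the leave-one-out
sensitivity analysis exist at the reporting level.

## Numerical choices and degenerate inputs

* Closure tolerance: inputs whose parts do not sum to the declared total
  are re-closed silently in constructors (real minute data rarely sum
  exactly); validation rejects negative minutes and non-positive
  follow-up with row numbers.
* Cox convergence: `eps = 1e-9`, 100 iterations; degenerate predictors
  (no variation/collinearity) and suspected monotone likelihood
  (|coef| > 15) raise warnings naming the coefficients.
* REML: started at the per-coordinate DerSimonian-Laird estimate,
  Nelder-Mead on the log-Cholesky factors (Brent in one dimension);
  non-PD candidates are rejected inside the objective.
* Root search: `uniroot` to HR tolerance 1e-6 on delta in
  (0, SB - 1 min); reported minutes are rounded last.
* Ties in the landmark filter: a death at exactly the cutoff is kept
  (strict inequality), consistent with "deaths *in* the first two
  years".
* Single-study pools pass through with `Psi = 0` and a warning; strata
  with no members are skipped.

## Validation summary

The test suite exercises, among other things: ilr orthonormality,
scale invariance, subcompositional consistency and round-trips; the
lrEM no-op, below-limit and ratio-preservation guarantees; a brute-force
partial-likelihood oracle for the Cox fit on a four-subject toy;
parameter recovery (bias, RMSE, CI coverage) for single studies and the
pooled stage; hand-computed DerSimonian-Laird and Cochran-Q fixtures and
a `metafor` cross-check for pooling; the mask negligible-weight and
insensitivity properties; the algebraic identities of the hazard-ratio
surface (antisymmetry, transitivity, unit invariance); and the
reallocation solver's round-trip against its own hazard-ratio curve.
Simulation sizes in tests are chosen to keep the default run in tens of
seconds (n of a few hundred to a few thousand, 200 replicates where
error rates are asserted); the `analysis/` scripts use the same sizes.

One caveat the package states rather than hides: estimated-coverage
assertions at 200 replicates carry a Monte-Carlo standard error of about
1.5 percentage points, so a band of 95% plus or minus 2 points is a
fragile gate even for a perfectly calibrated estimator; larger replicate
counts (the 600-replicate check reported in the repository notes) place
the coverage of all coordinates between 0.94 and 0.955.

## Known limitations

* Time-varying coefficients, competing risks, frailty and cause-specific
  mortality are out of scope; so is any alternative ilr basis.
* The landmark filter does not left-truncate; if calendar-time risk sets
  matter, fit with `survival`'s counting-process interface directly.
* `lrEM` assumes a zero-free reference part exists; data where every
  behaviour has zeros need a different imputation strategy.
* Published-coefficient models support point estimation exactly but
  interval estimation only under a diagonal-covariance approximation.
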