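---
title: "Distributed-lag non-linear modelling of ENSO impacts on oil palm yields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed-lag non-linear modelling of ENSO impacts on oil palm yields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Oil palm productivity in Malaysia is reported monthly at the estate level:
fresh fruit bunch (FFB) yield in t/ha/month, the oil extraction rate (OER)
in percent, and their product, oil yield. The El Niño Southern Oscillation
(ENSO) — summarized by monthly indices such as MEI, ONI, the Niño
sea-surface-temperature anomalies, negative SOI and BEST — drives Malaysian
rainfall and temperature anomalies with delays of many months, and fruit
development itself integrates conditions over roughly the two years before
harvest. The scientific question is therefore intrinsically a
*distributed-lag* one: what is the cumulative effect on this month's yield
of the ENSO state at every lag 0..L, allowing the effect to be non-linear
in the index value?

`ensopalm` implements that analysis as a reusable pipeline. Because the
underlying administrative records are restricted, the package also ships a
synthetic estate-month panel generator with a *known* exposure-lag-response
surface, so that every inferential claim the package makes can be tested by
parameter recovery, coverage and type-I-error simulations rather than by
eyeballing.

## The model

For estate $i$, state $s(i)$ and calendar month $t$,

$$ y_{it} = \alpha + \sum_{j,k} \beta_{jk} W_{t,(j,k)} + \gamma' z_{it}
   + \mu_{m(t)} + \nu_{s(i)} + \varepsilon_{it}, $$

where $W$ is the DLNM *cross-basis* of the ENSO index, $z_{it}$ are
LASSO-selected covariates, and $\mu$, $\nu$ are calendar-month (12 level)
and state (13 level) fixed effects. The cross-basis row for month $t$ is

$$ W_{t,(j,k)} = \sum_{\ell=0}^{L} b_j(x_{t-\ell})\, c_k(\ell), $$

with $b$ a cubic B-spline basis in exposure intensity and $c$ a B-spline
basis in lag with knots equally spaced on the log-lag scale (`log_knots`:
knots at $L^{i/(nk+1)}$), concentrating flexibility at short lags. The
model is a *parametric* additive model: all smoothness lives in the
cross-basis, no penalized smoothing is added. That keeps the Gaussian AIC
exact and every reported quantity a linear contrast of OLS coefficients.

Associations are reported relative to the neutral index value $x_0 = 0$.
The cumulative effect of exposure $x$ is $\Delta(x) = z(x)'\beta$ with
contrast $z(x) = \sum_\ell (b(x) - b(x_0)) \otimes c(\ell)$, its standard
error the delta-method form $\sqrt{z'Vz}$, and 95 % intervals
$\Delta \pm 1.96\,\mathrm{SE}$ (pointwise; no simultaneous bands, matching
the presentation convention of this literature). Lag-specific effects use
$c(\ell)$ in place of the lag sum, and summing them over integer lags
reproduces $\Delta(x)$ exactly — an identity the tests assert at 1e-10.
Headline contrasts are evaluated at $x = -1$ (moderate cool phase) and
$x = +2$ (strong warm phase); cumulative effects over lags 0..L divide by
$L+1$ for a per-month equivalent.

### Parameters that matter

* `L` — maximum lag in months; candidates (default 10 and 23) are compared
  by the Gaussian ML AIC, $n\log(\mathrm{RSS}/n) + 2(p+1) + n(1+\log 2\pi)$,
  with ties broken toward fewer lags. The 23/10-month windows mirror the
  outcome-specific windows the yield literature reports for FFB/oil and
  OER.
* Exposure basis — cubic, internal knots at the 25/50/75 % quantiles of the
  observed exposures, no intercept (the model intercept absorbs it),
  boundary the observed exposure range. The boundary is a hard wall:
  contrasts outside it error rather than extrapolate.
* Lag basis — cubic with intercept and three log-scale knots. Because it is
  only evaluated at the $L+1$ integer lags, its dimension is capped at
  $L+1$ (knots, then degree, are reduced for short windows); otherwise the
  cross-basis would be rank deficient by construction.
* Subgroup comparisons use the two-sample z-test
  $(\beta_1-\beta_2) \pm 1.96\sqrt{SE_1^2+SE_2^2}$ with significance level
  0.05, 0.025, 0.0125 for 2, 3, 5 subgroups; other counts follow the same
  $0.05/(n-1)$ rule (so 4 groups use 0.05/3 — the rule is stated only at
  those three counts, and this is the unique harmonic extension consistent
  with them).

### Covariate screening

Candidate confounders (labor intensity, fertilizer investment, tree-age
profile, soil score, fertilizer/crude-palm-oil prices, CPI, exchange rate,
COVID case counts, lockdown) are screened per outcome by a Gaussian LASSO,
$\tfrac1{2n}\lVert y - \beta_0 - X\beta\rVert^2 + \lambda\lVert\beta\rVert_1$,
solved by cyclic coordinate descent on the Gram matrix with standardized
columns. $\lambda$ is chosen at the *minimum* mean 10-fold CV error (the
one-SE rule is deliberately not used: the procedure being mirrored states
the minimum). Missingness is handled upstream as explicit categories;
missing-or-zero fertilizer investment forms the reference level. Three
structural rules are enforced rather than assumed: the exposure cross-basis
is never passed to screening (the exposure of interest cannot be screened
away — the functions refuse a `crossbasis`), month/state fixed effects do
not enter the LASSO and are always retained downstream, and screening is
per outcome.

### Random-intercept robustness fit

Estates are observed repeatedly, so a robustness fit adds a Gaussian estate
random intercept. For an identity-link Gaussian outcome the
penalized-quasi-likelihood scheme coincides with the linear mixed model, so
estimation delegates to a mature REML solver (`lme4`) behind the same fit
interface; on balanced one-way data the REML variance components equal the
ANOVA moment estimators $(\mathrm{MSB}-\mathrm{MSW})/m$, which the tests
use as a closed-form oracle. Writing a bespoke WLS/variance-update loop
would re-implement exactly this estimator with worse numerics.

## The synthetic world

`sim_config()` states the world once; tests never move it:

* 13 states, 102 panel months (2015-01..2023-06), estates spread over all
  states; mean FFB yield 1.36 t/ha/month and mean OER 18.71 % by
  construction (the systematic part of each outcome is centered before the
  mean is added).
* ENSO: one series per month shared by all estates — identification of lag
  effects comes from time variation only, as in the real design. The series
  is stationary AR(1) (coefficient 0.8, innovation SD 0.54, hence marginal
  SD 0.9, a realistic index scale) plus sustained event offsets: a strong
  warm event 2015-06..2016-04 (+1.5), a cool event 2020-08..2021-03 (-1.0)
  and a warm excursion in mid-2023 (+1.0), echoing the events of the study
  period. Several configurations can share one realization via `enso_seed`
  (strata of a single region).
* Truth surface: $f(x,\ell) = -(\gamma_+ \max(x,0)^2 + \gamma_-
  \min(x,0)^2)\,w(\ell)$ with $w \ge 0$, $\sum w = 1$ — an inverted-U in
  $x$, null at the reference, with the cool side steeper
  ($\gamma_- = 0.2 > \gamma_+ = 0.1$), and a geometric lag profile over
  lags 0..12 by default (strictly inside the 23-lag search window so lag
  selection is testable). `true_cumulative()` is the closed-form oracle.
* Seasonality: fixed monthly shape with a February trough and a joint
  September-October peak, centered, amplitude 0.15 t/ha.
* Heterogeneity and noise: state effects (SD 0.15), estate intercepts
  (SD 0.25), idiosyncratic noise (SD 0.35, optionally AR(1) within estate —
  off by default since within-estate yield autocorrelation is not
  documented for these records), yields truncated at 0 after noise.
* Covariates: small linear true effects for labor intensity, fertilizer
  investment, soil score and tree age; prices, CPI, exchange rate, COVID
  counts and lockdown have *zero* true effect — screening has genuine
  positives and negatives to find. Fertilizer cost is unrecorded in the
  first and last panel years, soil scores are missing for ~45 % of
  estates, mimicking the reporting gaps such panels have.
* Weather: per-state quadratics in the 2-month-lagged index (air and soil
  temperature around 26-28 °C, precipitation around 7.09 mm/day) plus
  noise — the teleconnection structure the descriptive stage fits back.

What the generator does **not** emulate: spatially correlated weather
fields, estate entry/exit, mill-level OER aggregation (estate OER is drawn
directly), reporting error, and any real index history. A green test
therefore establishes that the estimator recovers the stated world's
truth — not that any particular real-world estimate is correct.

## Numerical choices

* B-spline evaluation is a vectorized Cox-de Boor recursion with the upper
  boundary closed (left-continuous at $x = \max$); it is oracle-tested
  against an independent spline-design evaluation at 1e-10 and the
  cross-basis against a naive double loop at 1e-12.
* The OLS engine solves via Cholesky of $X'X$ with an explicit rank check;
  aliased columns are named in the error. Model-based
  $V = \hat\sigma^2 (X'X)^{-1}$ with $\hat\sigma^2 = \mathrm{RSS}/(n-p)$;
  no cluster adjustment by default (the convention being mirrored reports
  model-based intervals; note the exposure varies only by month).
* `fit_cells()` collapses the no-covariate model onto period-by-state cells
  (weighted OLS on cell means, within-cell sums of squares folded into the
  RSS). This is the same estimator exactly — equal $\beta$, $V$, RSS and
  AIC in exact arithmetic — and makes multi-million-row simulation fits
  cheap; the equivalence is itself a test.
* Coordinate descent converges on the max coefficient change at 1e-8
  relative to the outcome scale, with warm starts along the λ path
  (100 log-spaced values from $\lambda_{max}$ down to $10^{-4}\lambda_{max}$).
* Quantile groups use linear-interpolation sample quantiles with ties to
  the lower group; precipitation converts at a fixed 30-day month
  (7.09 mm/day → 212.7 mm/month).
* All randomness flows from one root seed through fixed offsets (index
  series: `enso_seed`; panel body: seed + 1; CV folds: seed + 2), so every
  stage is independently reproducible and a rerun is byte-identical.

## Design decisions that were genuinely open

* The "GAM + DLNM" combination is realized as a fully parametric additive
  model (above): no penalized smooths besides the cross-basis. This keeps
  AIC comparisons across lag windows exact and contrast covariances
  closed-form.
* The lag-knot formula is fixed as $L^{i/(nk+1)}$; the source names a
  log-knot function without printing its formula. The formula is exposed
  (`log_knots`) and the specs are overridable.
* Whether the lag basis carries an intercept and the exposure-dimension
  df are unstated in the mirrored procedure; the defaults above follow
  common DLNM practice and are configurable per fit.
* Subgroup strata reuse the pooled covariate selection and share pooled
  basis specs and boundary, so cumulative effects are directly comparable;
  per-stratum reselection would confound effect modification with
  selection noise.
* Stratum comparisons are each-versus-reference (first level), not
  all-pairs, matching how such contrasts are narrated (e.g. lowest vs
  highest labor intensity).

Two properties of this world deserve emphasis because they shaped the test
design. First, the fertilizer covariate is a *time-varying confounder by
construction*: investment is unrecorded (and coded to the reference level)
in the first and last panel years, which are also warm-event years, so a
fit that omits covariates absorbs a spurious year-level yield shift into
the exposure surface. Exposure-recovery simulations therefore either
adjust for covariates or switch their effects off; a noiseless audit
confirms the cross-basis machinery itself recovers the planted cumulative
effects essentially exactly (|error| < 1e-3 with noise off). Second, the
exposure-basis boundary matters: extending it far beyond the observed
index range leaves the unknotted spline tail free to extrapolate and
biases contrasts near the data edge — the observed-range default exists
for statistical, not merely defensive, reasons.

## Known limitations

* With 102 panel months and a smooth AR(1) index, a 42-parameter surface
  is weakly identified: standard errors of cumulative contrasts at
  $x = 2$ are large unless the panel is wide. Coverage is nominal (the
  tests verify 93-97 % across 200 null panels), but *power* for subgroup
  differences of realistic size requires tens of thousands of estates —
  the effect-modification acceptance simulation documents this limit
  honestly rather than shrinking the stated noise.
* AIC selection among lag windows of equal cross-basis dimension reduces
  to an RSS comparison; windows that nest the truth are distinguished by
  approximation error only, so the selected window concentrates on, but
  does not always equal, the shortest true window.
* Model-based intervals assume independent errors given the fixed effects;
  with estate random intercepts present they are conservative for
  month-level contrasts. The robustness fit quantifies, but does not
  remove, this.
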