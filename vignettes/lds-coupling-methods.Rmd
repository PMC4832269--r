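---
title: "Latent difference score coupling of brain volumes and cognition: models, generator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent difference score coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
coupled latent difference score (LDS) model, the estimator, the synthetic
cohort generator and its anchoring to published cohort moments, the
numerical choices, and the places where the design was genuinely open.

## The model and its assumptions

Each cognitive domain (fluid intelligence, memory, processing speed) is a
latent factor measured at two waves (mean ages 73 and 76) by the same tests.
Digit–symbol substitution and symbol search indicate speed but cross-load on
fluid intelligence. Strong measurement invariance — equal loadings *and*
equal intercepts across waves — is imposed so that latent means are
comparable over time; without intercept invariance a latent mean change is
not interpretable. Identification fixes the first loading of each factor to
1 (reference-indicator scaling); reported standardized estimates are
computed afterwards from the implied moments, so this choice is
consequence-free for the quantities of interest.

Change is modelled as an exact latent difference: wave-2 variable = wave-1
variable + Δ, with both incoming paths fixed to 1 and the wave-2 residual
variance and intercept fixed to 0. We read the construction this way — an
exact difference, not a residualized regression slope — because that is what
the unit-path diagram and the LDS literature define; the change score then
owns a mean (mean change), a variance (individual differences in change) and
free covariances with every level and every other change score. Those
covariances, standardized, are the level–change and change–change
correlations the analysis is about. Brain volumes enter as manifest
variables (one measurement per wave), so their change scores absorb
measurement error; the cognitive change factors are error-free in the
factor-analytic sense.

All variables are residualized for sex and age-in-days (cognitive variables
against age at cognitive testing of their wave, volumes against age at MRI)
before modelling. Residualization is *mean-preserving* by default: each
variable keeps its available-case mean, because centring every variable at
every wave would erase the longitudinal mean structure and force all
estimated mean changes to zero. A `center = TRUE` switch provides plain
zero-mean residuals for uses where the mean structure is irrelevant.

Estimation is full-information maximum likelihood: each row contributes the
multivariate-normal log-density of its observed subset, which is consistent
when dropout depends only on observed modelled variables (MAR). The model
χ² is `2(llₛₐₜ − llₘₒdₑₗ)` against a saturated model estimated by EM on the
same rows; CFI/TLI use an independence-with-means baseline, also estimated
under FIML (its MLE factorizes into univariate moments). RMSEA uses
`sqrt(max(T − df, 0)/(df·n))`.

## Degrees of freedom audit

With correlated uniquenesses (each test's residual allowed to covary with
itself across waves — standard for repeated indicators and on by default),
all level/change covariances free, and the identification rules above, the
TBV model has 100 free parameters against 377 observed moments, df = 277,
and the three-tissue model 146 against 495, df = 349. The published versions
of these models report df = 276 and 348 — exactly one less in both cases, so
the original analysis freed one additional parameter somewhere in the shared
cognitive part (the text does not say which; a residual covariance between
the two cross-loading speed tests is one plausible candidate). We report our
df rather than absorbing the discrepancy, and the constant +1 offset across
both models is asserted in the test suite.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without the
original cohort data. It draws from *exactly* the LDS structure the models
fit — the package's central oracle: `population_moments()` (direct factor
algebra) must equal `implied_moments()` of the built models at
`generating_theta()`, and fitting a large simulated cohort must recover the
generating values.

Anchoring, in order of authority:

* **Loadings and raw moments per test**: the published wave-1 descriptive
  table (standardized loadings 0.427–0.795, cross-loadings 0.316/0.384).
  Residual variances are 1 − communality on the standardized scale
  (communality uses the wave-1 factor correlations), then rescaled to raw
  SDs — so the published loadings hold by construction.
* **Wave-1 level correlations** among the three factors and four volumes:
  the published age-73 correlation matrix (sex/age-controlled, which is the
  scale the generator's core lives on).
* **Stabilities and level–change correlations**: both are printed, and both
  are honored exactly by *deriving* each variable's change SD from
  stability = (1 + rc)/sqrt(1 + c² + 2rc), where r is the level–own-change
  correlation. For the volumes r is printed (−0.121 TBV, −0.182 GM, −0.010
  NAWM, 0.596 WMH); for the cognitive factors it is not printed and defaults
  to 0. The resulting change SDs (per 3-year interval, in wave-1 SD units)
  are roughly 0.26 (TBV), 0.39 (GM), 0.33 (NAWM), 0.38 (WMH), 0.25 (fluid),
  0.50 (memory), 0.57 (speed). A fixed change SD of 0.3 for all cognitive
  factors was considered and rejected: it is incompatible with the printed
  memory and speed stabilities (0.896, 0.867), whose minimum attainable
  stability at c = 0.3 is 0.958.
* **Mean changes**: volumes in cm³ across the study (−19.12, −9.28, −14.46,
  +4.06); cognitive factors in wave-1 SD units per year (−0.074, −0.058,
  −0.147) times the 3-year nominal interval.
* **Couplings**: all printed level–change and change–change correlations
  between brain and cognition, including the non-significant ones where a
  value is printed. Where only a family mean is printed the defaults split
  it consistently with the printed mean and the sensitivity analyses
  (memory/speed level → ΔTBV as 0.190/0.128 around the printed mean 0.159;
  the three cognitive levels → ΔNAWM as 0.140/0.175/0.195 around 0.170).
  Speed level → ΔWMH is set to −0.189: the printed magnitude with the sign
  of the described direction ("higher speed, less WMH growth"). Couplings
  the study does not print are 0, with two exceptions derived from volume
  additivity (TBV ≈ GM + NAWM + WMH): TBV's level and change couplings with
  the component tissues. These only matter for joint simulation — no fitted
  model contains both TBV and its components.
* **Cognitive change–change correlations**: the printed mean 0.634 is used
  for all three pairs (per-pair values are not printed).

The assembled 14×14 core correlation matrix (7 levels + 7 changes) is
marginally non-positive-definite — unsurprising, since its blocks come from
two different fitted models plus out-of-model correlations. The constructor
repairs it to the nearest correlation matrix (Higham projection via
`Matrix::nearPD`); at the defaults the largest entry change is ~0.003 and
the repair magnitude is recorded on the config (`pd_adjustment`). User edits
that break positive definiteness are repaired the same way, with a message.

Sex and age are added *on top* of the core draw: wave-specific male/female
mean offsets for the volumes taken from the published sex-split table (so
males decline faster in TBV and GM, as published), and small linear
age-in-days trends (default ±0.05 SD per year of age) around each
assessment's mean age. The published volume SDs pool the sexes, so the core
scale removes the sex-offset variance before scaling; simulated raw volumes
then reproduce the published mean and SD, and residualization returns the
data to the core scale exactly. Test residuals correlate 0.3 across waves
(a conventional retest value for test-specific variance; not printed, free
default).

Attrition is missing-at-random on the *observed* wave-1 cognitive composite
(z-scored mean of the 12 wave-1 tests) through a logistic model whose
intercept is calibrated to the target dropout fraction (19.5% cognitive,
34.2% imaging at wave 2; 75.9% wave-1 imaging coverage). The default slope
of 0.9 per composite SD reproduces the published returner/non-returner
difference (≈0.5 SD on latent fluid intelligence). Because the composite is
a function of observed model variables, FIML is consistent under this
mechanism while complete-case analysis is not — the test suite demonstrates
the complete-case bias in the TBV change mean. MMSE scores (floor/ceiling,
≈2.3% below the conventional cut-off of 24 per wave) and dementia flags
(≈3.6%, preferentially low-cognition) support the sensitivity-exclusion
analyses.

What the generator does **not** emulate: practice effects on repeated tests,
item-level MMSE structure, non-normal test distributions (WMH can optionally
be given a moment-matched lognormal-shaped marginal; the analysis scale is
normal), per-subject scan intervals (the published mean interval is 3.7
years but the printed annualized columns divide by the nominal 3.0, which is
therefore the default divisor), and not-missing-at-random dropout. Passing
recovery tests on this generator therefore validates the estimator and
pipeline under the model's own assumptions; it cannot certify robustness to
violations real cohorts may show.

## Numerical choices

* **Scaling.** Data are internally rescaled per variable (wave pairs pooled
  so invariance constraints stay consistent); latent scales are resolved
  through fixed unit paths. Estimates are mapped back exactly — the model
  class is closed under per-variable rescaling. If a user constraint ties
  parameters across incompatible scales the fit silently falls back to the
  raw scale.
* **Transforms and bounds.** Variances are optimized on the log scale
  (bounded below at 1e−9); covariances, loadings and means are free.
  Non-positive-definite implied covariances are rejected with a large
  penalty value.
* **Optimization.** Quasi-Newton (`nlminb`) with analytic gradients
  obtained by chaining the pattern-wise moment-space gradient through the
  RAM structure; 5 jittered restarts by default, ties broken by best
  log-likelihood then smallest gradient norm. Each start is "polished" by
  restarting the optimizer at its own solution (resetting the Hessian
  approximation) until the gradient criterion is met; convergence requires
  max |∂(−2ll)/∂θ| ≤ tol·n with tol = 1e−4. Heywood cases (variances at the
  boundary) are flagged, never silently accepted.
* **Standard errors.** Inverse observed information, computed as central
  finite differences *of the analytic gradient* (step 1e−4 relative), which
  makes the Hessian cheap even for the 146-parameter model. Standardized
  estimates get delta-method SEs on the correlation metric — our choice
  where the original software's convention is not documented.
* **Saturated model.** EM on missing-data patterns to a relative
  log-likelihood change below 1e−10; closed-form for complete data.
* **Missing-data patterns** are grouped once and summarized by
  (n, mean, scatter), so likelihood and gradient cost is per pattern, not
  per row; the 30-variable model fits a complete-case n = 20,000 cohort in
  a few seconds on one CPU.

## Open design choices and their resolutions

* **Correlated uniquenesses**: included by default (repeated indicators),
  switchable; the df audit above keeps the choice inspectable.
* **Equality tests on the correlation metric**: constraining raw
  covariances equal is not the same hypothesis as constraining correlations
  when variances differ. The package refits the model in a standardized
  parameterization (every exogenous level and change variable has unit
  variance, with scale carried by free paths; both parameterizations imply
  the same moment structure and df) and constrains there, yielding clean
  1-df χ² tests. Pairs are auto-selected by the rule of testing only where
  at least one member is significant at raw p < .05.
* **FDR families**: one family per model, pooling the level–level,
  level–change and change–change p-values of that model; loading and mean
  p-values are not pooled. Report stars follow raw p with adjusted p
  adjacent, since both regimes are of interest.
* **Sex moderation** uses Bartlett factor scores and product regression
  rather than latent product estimation. The approximation attenuates
  interaction estimates slightly (factor-score reliability < 1); the
  recovery test shows a true male–female coupling difference of 0.15
  recovered as ≈0.12–0.14. The report footer notes this.
* **Analysis n for fit indices** defaults to the rows actually used; the
  published RMSEA values are reproduced from the printed χ²/df with the
  full cognitive-wave n of 866, consistent with how they were evidently
  computed.

## Precision limits and problem sizes

At n = 20,000, correlations involving the fluid-intelligence change factor
carry sampling SEs near 0.04 — a direct consequence of honoring the printed
fluid stability of 0.969, which leaves little change variance to correlate.
Recovery tests therefore hold those parameters to three delta-method SEs,
while all precisely identified parameters (stabilities, volume couplings,
loadings, mean changes) are held to absolute tolerances of 0.01–0.03. The
test suite uses one shared simulated cohort of n = 20,000 for recovery, 50
replicates of n = 1,000 for type-I calibration of the zero-coupling
generator (raw rejection rate checked against its nominal 5%), and smaller
cohorts (n = 3,000–10,000) for pipeline behaviour; these sizes are the
package's chosen trade-off between Monte-Carlo precision and a test suite
that runs in a couple of minutes.

A final practical note on the FDR step: Benjamini–Hochberg adjusted
p-values are not a fixed point of re-adjustment (re-running the step-up on
already-adjusted values inflates them), so adjusted values should be
computed once from raw p-values, as `run_analysis()` does.

## Known limitations

Two waves identify means and variances of change but not its trajectory
shape; the generator and models are silently linear-in-time. The estimator
assumes multivariate normality; robust/scaled test statistics and weighted
least squares are out of scope, as are bootstrap standard errors, ordinal
indicators, and ICV-proportional or log-WMH variable transformations (config
hooks exist but are unvalidated). Sex moderation by factor-score regression
is approximate, as discussed. And the synthetic cohort, however carefully
anchored, is a statistical replica of published summary moments — not a
substitute for the cohort itself.
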