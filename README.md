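# ldscoupling

Two-wave **latent difference score (LDS) structural equation models** for
studying how changes in brain tissue volumes couple with changes in cognitive
abilities in ageing cohorts — total brain volume (TBV), grey matter (GM),
normal-appearing white matter (NAWM) and white matter hyperintensity (WMH)
volumes on the brain side; latent fluid intelligence, memory and processing
speed factors (12 tests, strong measurement invariance) on the cognitive side.
It is written for quantitative researchers in cognitive ageing and
epidemiology who want a fully scriptable, testable version of this analysis,
including a synthetic-cohort generator so every stage can be validated by
parameter recovery when the original cohort data are not available.

## The model

For each cognitive domain a latent factor is measured at both waves by the
same tests with loadings and intercepts constrained equal across waves
(strong invariance; two paper-and-pencil speed tests also cross-load on fluid
intelligence). Change is a latent difference score: for a wave-1/wave-2 pair
(η₁, η₂),

    η₂ = η₁ + Δ,        (paths fixed to 1, wave-2 residual and intercept 0)

so Δ carries its own mean, variance, and free covariances with every level
and every other change score. Brain volumes enter as manifest variables with
the same unit-path construction. The implied moments follow the RAM
parameterization

    Σ = F (I − A)⁻¹ S (I − A)⁻ᵀ Fᵀ,   μ = F (I − A)⁻¹ m,

and estimation is full-information maximum likelihood (FIML): each subject
contributes the multivariate-normal log-density of whatever subset of
variables they have, which is valid under missing-at-random dropout. Fit is
summarized by the likelihood-ratio χ² against an EM-estimated saturated
model, RMSEA, and CFI/TLI against an independence baseline. The couplings of
interest are the **level–change** correlations (does the wave-1 level of one
variable predict subsequent change in another?) and **change–change**
correlations (do the two variables change together?), with
Benjamini–Hochberg FDR correction pooled within each model.

Model A couples the three cognitive domains with TBV (26 observed variables,
4 change scores); Model B replaces TBV with GM, NAWM and WMH (30 observed
variables, 6 change scores). All variables are residualized for sex and age
in days (wave- and modality-matched) before modelling.

## Worked example

```r
library(ldscoupling)

config <- generator_config()              # defaults = published cohort moments
cohort <- simulate_cohort(config, n = 5000, seed = 42)
cohort <- flag_exclusions(cohort, seed = 43)          # MMSE + dementia flags
cohort <- apply_attrition(cohort, "MAR", seed = 44)   # dropout tracks low cognition

report <- run_analysis(cohort, model = "A", seed = 1)
report
#> correlation_report (Model A), n = 5000, exclusion = none
#>   chisq(277) = 307.862, RMSEA = 0.005, CFI = 0.999, TLI = 0.999
#>   change-change correlations:
#>     d_tbv     ~ d_fluid    r =  0.186 (0.060)**  p_fdr = 0.004
#>     d_tbv     ~ d_memory   r = -0.108 (0.043)*  p_fdr = 0.022
#>     d_tbv     ~ d_speed    r =  0.151 (0.034)***  p_fdr = 0.000
#>     d_fluid   ~ d_memory   r =  0.698 (0.104)***  p_fdr = 0.000
#>     d_fluid   ~ d_speed    r =  0.658 (0.095)***  p_fdr = 0.000
#>     d_memory  ~ d_speed    r =  0.647 (0.053)***  p_fdr = 0.000

report$annualized
#>   volume mean_change per_year sd_per_year pct_per_year
#> 1 tbv          -19.8    -6.60     -0.0722       -0.665
```

The report shows that (a) FIML reproduces the generating couplings under
cognition-dependent dropout — e.g. total brain volume change correlates
about 0.15 with speed change and about −0.11 with memory change, the values
the generator encodes; (b) total brain volume declines ~6.6 cm³ (≈0.67% of
the wave-1 mean) per year. `r = ...` values are standardized estimates with
delta-method standard errors in parentheses; stars follow raw p, the
adjacent column the FDR-adjusted p.

Whether two couplings differ is a 1-df χ² test with the pair constrained
equal on the correlation metric:

```r
equality_tests(cohort, "A",
               pairs = list(c("d_speed", "d_tbv", "d_memory", "d_tbv")), seed = 1)
#>            cor1           cor2  est1   est2 chisq_diff df_diff        p
#> 1 d_speed~d_tbv d_memory~d_tbv 0.151 -0.108       28.4       1 9.93e-08
```

Further entry points: `fit_model()` / `standardized_solution()` for direct
SEM work, `sex_moderation()` for factor-score interaction tests,
`recovery_experiment()` for simulate-and-refit calibration studies,
`write_report()` / `write_cohort()` for file output, and thin command-line
wrappers under `inst/scripts/`.

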