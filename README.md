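# firipm

Bayesian integral projection modelling for a declining, size-structured
subalpine fir population, with drought covariates.

Long-lived conifers such as the Korean fir decline slowly: whether a stand is
shrinking, and which trees' survival or growth matter most for reversing the
trend, can only be read out of individual-level census data through a
demographic model. `firipm` is for population ecologists and conservation
analysts who have (or want to emulate) biennial diameter censuses — tree id,
DBH, alive flag, recruit flag — plus monthly weather, and who want the full
chain from raw census rows to a defensible population growth rate with
uncertainty, forecasts of the future size structure, a drought attribution,
and a ranking of which vital rates drive the trend.

## The model

The population state is the DBH distribution *n(x, t)*, projected per
two-year census interval by a kernel

    n(y, t+1) = ∫ K(y, x) n(x, t) dx ,   K = P + F

* **Survival–growth:** `P(y,x) = s(x) g(y|x)` with
  `logit s(x) = β₀ₛ + β₁ₛ x` (Bayesian logistic regression) and
  `y ~ Normal(β₀g + β₁g x, σg)` (Bayesian linear regression), both under
  weakly informative Normal(0, variance 5) priors (Half-Normal(5) on σg).
* **Fecundity:** `F(y,x) = R f_rec(y) m(x)` — observed per-capita
  recruitment rate `R`, Beta(1.3, 2) recruit sizes, and
  `m(x) ∝ √max(x − 5, 0)` above a 5 cm reproductive threshold.
* **Discretisation:** 100 midpoint cells on `[0.9·min, 1.1·max]` DBH, growth
  mass integrated per destination cell and renormalised (eviction
  correction), so every column of `P` sums exactly to `s(x)`.
* **λ** is the dominant eigenvalue of `K`; parameter uncertainty is
  propagated by a 1000-draw posterior kernel ensemble.
* **Drought:** SPEI-24 from monthly weather (FAO-56 Penman–Monteith PET,
  water balance, 24-month sums, log-logistic standardisation), linked to
  log λ by a Bayesian observation-error regression
  `ŷₜ ~ N(α + β x̃ₜ, σ_obs,t)`.
* **Attribution:** SHAP values on a gradient-boosted surrogate of the
  parameter→λ map, plus perturbation elasticities of λ to survival and mean
  growth per DBH class.

A synthetic census/weather generator reproduces exactly these generative
assumptions, so the whole pipeline is testable by parameter recovery without
any field data.

## Worked example

```r
library(firipm)

# 1. simulate a censused population from the shipped vital-rate estimates
census <- simulate_census(vital_rate_truths(), n0 = 1000, seed = 1)

# 2. fit the 2018-2020 interval
st    <- mcmc_settings(seed = 1)
fit_s <- fit_survival(census, 2, st)
fit_g <- fit_growth(census, 2, st)
rec   <- estimate_recruitment(census, 2)
tidy(fit_s)
#> # A tibble: 2 × 8
#>   parameter      estimate std.error hdi_low hdi_high  rhat   ess pass
#>   <chr>             <dbl>     <dbl>   <dbl>    <dbl> <dbl> <dbl> <lgl>
#> 1 surv_intercept   3.41      0.559   2.37      4.57   1.00 1711. TRUE
#> 2 surv_slope       0.0806    0.0519 -0.0111    0.186  1.00 1673. TRUE
rec
#> Recruitment: 32 recruits / 981 parents = 0.0326 per individual per interval

# 3. kernel and growth rate from the published parameter table
grid <- size_grid(3, 40)
ipm_kernel(vital_rate_truths()[2, ], grid,
           fecundity_config(m_normalization = "none"))
#> IPM kernel (100 x 100): lambda = 1.0396 per interval (annualised 1.0196)

# 4. posterior uncertainty in lambda for the fitted interval
lambda_ensemble(fit_s, fit_g, rec, grid, n_draws = 1000, seed = 1)
#> Lambda ensemble (1000 draws): mean 1.0127 (SD 0.0040); mean-kernel lambda 1.0125
```

Reading the numbers: the survival fit recovers the generating coefficients
(truth 3.64 and 0.033, both inside the 95% HDIs) with clean diagnostics; the
recruitment ratio estimates the generating rate 0.034; the kernel assembled
from the published 2018–2020 parameters gives λ ≈ 1.04 per two-year interval
(a growing interval); and the ensemble around the *fitted* parameters puts
λ at 1.013 ± 0.004 for this synthetic population.

The whole pipeline — simulate, fit all four intervals, ensembles, mean
kernel, projection to 2040, SPEI, drought regression, SHAP importance,
elasticities, cross-validation — runs as one seeded call:

```r
run <- run_ipm_pipeline(pipeline_config(n0 = 1000, seed = 42))
run$interval_summary
glance(run$regression)
```

Plot methods (`autoplot()` on kernels, ensembles, elasticity profiles,
importance tables, regressions; `plot_projection()`) return ggplot objects.

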