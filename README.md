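# guanacopop

Tools for analysing long-term strip-transect monitoring of guanaco (*Lama
guanicoe*) populations, built around a 36-year time series from a 2000 km²
sheep ranch in Tierra del Fuego. The package asks the classic population
question for this system: is the finite rate of increase λ regulated by the
population's own density, by livestock, or by climate — and, if density wins,
what carrying capacity does the fitted relationship imply?

The pipeline has five stages, each usable on its own:

1. **Abundance** — the King strip-transect estimator (Leopold modification):
   for a survey counting *n* animals along *x* metres of transect with mean
   perpendicular sighting distance *y* over a study area *A*,

   N̂ = A·n / (2·y·x),

   with variance S² = n(1−p)/p² + n/(n+2) where p = n/N̂, and normal 95%
   confidence bounds.
2. **Demography** — one three-age-class (newborn, juvenile, adult)
   female-only projection matrix per annual transition, fitted to the total
   abundance series by sum of squares under a 50% sex ratio; λ for each year
   is the matrix's dominant (Perron) eigenvalue.
3. **Covariates** — linear interpolation of missing census years, natural-log
   abundances, and lagged climate means: the mean of the *T* years strictly
   preceding each focal year (precipitation *T* = 1…7, winter temperature
   *T* = 1).
4. **Regression** — a Pearson collinearity screen among predictors; because
   the lagged precipitation means are mutually correlated, seven multiple
   regressions of λ on {lnNtot, lnSheep, precipitation, winter temperature,
   precip_Tk, winter_temp_T1} are fitted with the lagged variants substituted
   one at a time and ranked by AIC; a simple regression λ ~ lnNtot tests
   density dependence directly, and its inversion at λ = 1 gives the
   carrying capacity K = exp((1 − a)/b).
5. **Synthesis** — a generator that simulates density-dependent
   age-structured trajectories observed through Poisson-thinned strip
   transects, so the entire pipeline can be validated by parameter recovery.

All user-facing functions take a data frame first and return tibbles; fitted
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

A full synthetic study, end to end:

```r
library(guanacopop)

sim <- simulate_trajectory(sim_config(seed = 2024))   # truth: a = 1.6373, b = -0.0552
est <- estimate_abundance(sim$surveys)
head(est, 3)
#>    year  N_hat     p     S2 ci_low ci_high
#> 1  1977 15300   0.21 57558. 14830.  15770.
#> 2  1978 17457.  0.21 65673. 16955.  17959.
#> 3  1979 20524.  0.21 77210. 19979.  21068.

fit <- fit_yearly_matrices(dplyr::select(est, year, N_hat))
fit
#> Per-year projection-matrix fit (stable mode): 35 transitions, SSQ = 7.5e-22, converged
#> lambda: min 0.9282, median 1.0478, max 1.1757

tab <- build_covariate_table(est, lambda_series(fit), sim$covariates)
simple <- fit_ols(tab, "lambda", "lnNtot")
simple
#> OLS fit: lambda ~ lnNtot  (n = 35)
#>   term        estimate std.error statistic   p.value
#> 1 (Intercept)   1.81      0.234       7.73  6.60e-09
#> 2 lnNtot       -0.0717    0.0220     -3.27  2.55e-03
#> R2 = 0.2442  F = 10.661 (p = 0.002552)  AIC = -95.547

carrying_capacity(simple, area_km2 = 2000)
#>        K density_per_km2
#> 1 79669.            39.8
```

The estimated abundances track the simulated truth (21% of the area is
surveyed, so p ≈ 0.21 each year); the matrix fit reproduces the annual
growth ratios essentially exactly (SSQ ≈ 0), and the simple regression
recovers a clearly negative density slope (here −0.072 against a generating
value of −0.055; a single 36-year replicate carries this much sampling
spread, which the test suite quantifies over 200 replicates). The implied
carrying capacity is the abundance at which the fitted line crosses λ = 1.

The lagged-regression family and the collinearity screen behind it:

```r
regression_family(tab)$summary   # seven models, AIC ascending
collinearity_screen(tab)         # which predictors may not share a model
```

With the published coefficients of the simple density-dependence regression
(intercept 1.6373, slope −0.0552), the equilibrium works out to

```r
carrying_capacity(area_km2 = 2000, intercept = 1.6373, slope = -0.0552)
#>         K density_per_km2
#> 1 103289.            51.6
```

about 103,000 guanacos, or 51 animals per km².

A command-line wrapper over the same stages lives at
`inst/cli/guanacopop.R` (stages `simulate`, `estimate-abundance`,
`fit-matrices`, `build-covariates`, `regress`, `run-all`; every run writes a
JSON manifest with its seed and configuration hash).

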