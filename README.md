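# mortclim

Two-stage modelling of temperature–mortality associations, with tools
for comparing two candidate daily temperature series (for example
weather-station records versus a gridded reanalysis product) fitted to
the same mortality data.

The package implements the workflow standard in multi-city
environmental epidemiology:

- **First stage (per city):** quasi-Poisson time-series regression of
  daily deaths on a distributed lag non-linear model (DLNM)
  cross-basis of temperature (natural cubic splines in both the
  exposure and 0–21-day lag dimensions), controlling for season/trend
  (natural spline of time, 8 df/year) and day of week; reduction of
  the fitted surface to the overall cumulative exposure–response
  curve; quasi-AIC.
- **Second stage:** multivariate multilevel meta-regression (REML)
  pooling the city curves with nested random effects (city within
  country × climate zone) and meta-predictors, returning best linear
  unbiased predictions (BLUPs) of each city's curve plus multivariate
  Cochran Q and I².
- **Impacts:** minimum mortality temperature (MMT) by grid search over
  the 1st–99th percentiles, attributable deaths and fractions split
  into cold and heat, Monte Carlo empirical confidence intervals with
  the MMT held fixed, and country/global aggregation with
  index-aligned samples.
- **Comparison:** Pearson correlation, bias and RMSE between the two
  exposure series, symmetric missingness alignment, and the relative
  fitting score `RFS = qAIC(reanalysis) − qAIC(station)` (positive
  values favour the station series) with per-country summaries.
- **Synthetic data:** a multi-city generator with a known V-shaped
  risk surface, geometric lag weights, NB1 overdispersed counts and a
  degradable "reanalysis" proxy (attenuated anomalies + noise), which
  records ground-truth attributable fractions so the whole pipeline
  can be validated end to end.

All heavy methodology (cross-basis, lag reduction, log-Cholesky REML
meta-regression, BLUPs) is implemented in-package on top of base R and
`splines::ns`, and is validated against brute-force oracles and
`metafor::rma.mv` in the test suite. See `vignettes/methods.Rmd` for
the full model specification and known limitations.

## Quick start

```r
library(mortclim)

cfg <- sim_config(n_cities = 8, years = 5, seed = 1)
res <- run_pipeline(cfg, n_mc = 500L)     # add outdir = "run1" to write CSVs

g <- res$impacts$station$global
sprintf("global cold AF (station): %.2f%% [%.2f, %.2f]",
        g$af_cold, g$af_cold_ci[1], g$af_cold_ci[2])
#> "global cold AF (station): 8.52% [6.73, 10.16]"
sprintf("global heat AF (station): %.2f%% [%.2f, %.2f]",
        g$af_heat, g$af_heat_ci[1], g$af_heat_ci[2])
#> "global heat AF (station): 1.99% [1.56, 2.38]"
res$truth$global[c("af_cold", "af_heat")]   # generator ground truth
#> $af_cold [1] 6.74...  $af_heat [1] 2.79...

subset(res$comparison_summary, group == "Global")
#>   group n median_rfs n_negative n_zero n_positive median_r
#>  Global 8   10.06472          2      0          6 0.987016

res$cities[[1]]
#> <city_record> city001 (country01, warm): 1826 days, 2010-01-01 to 2014-12-31
```

Lower-level entry points: `simulate_study()`, `fit_city()`,
`meta_dataset()` / `fit_meta()` / `compute_blups()`, `find_mmt()` /
`attributable_series()` / `monte_carlo_eci()` / `aggregate_impacts()`,
`agreement_metrics()` / `relative_fitting_score()`, and CSV / gridded
helpers `write_city_csv()`, `read_city_csv()`, `gridded_field()`,
`extract_nearest_cell()`, `hourly_to_daily()`.

## Tests

```r
# from the package root
devtools::test()
# or against an installed copy
testthat::test_dir("tests/testthat", package = "mortclim",
                   load_package = "installed")
```

`tests/testthat/test-acceptance.R` holds the acceptance criteria, one
block per criterion. Three assertions there (pointwise recovery of the
kinked ground-truth curve at scale, and the direction of the
degradation effect on heat AF) are expected to fail: they assert
properties that do not hold for a smooth-spline estimator of a
piecewise-linear truth, and are kept as stated rather than weakened.
The mechanism is documented in the vignette's limitations section.

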