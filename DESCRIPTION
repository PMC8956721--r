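Package: mortclim
Title: Two-Stage Modelling of Temperature-Mortality Associations from
    Competing Exposure Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating heat- and cold-related excess mortality
    from daily city-level time series using the two-stage design common in
    multi-city environmental epidemiology: first-stage quasi-Poisson
    regression with a distributed lag non-linear model (DLNM) cross-basis,
    reduction to the overall cumulative exposure-response association, and
    a second-stage multivariate multilevel meta-regression yielding best
    linear unbiased predictions (BLUPs) of city-specific curves. Includes
    minimum mortality temperature estimation, attributable numbers and
    fractions with Monte Carlo empirical confidence intervals, and a
    relative fitting score (difference in quasi-AIC) for comparing two
    candidate daily temperature series (e.g. weather-station records
    versus a gridded reanalysis product) fitted to the same mortality
    data. A synthetic multi-city data generator with a known risk surface
    supports validation of the whole pipeline without confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    MASS,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
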