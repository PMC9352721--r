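Package: flightwatch
Title: Butterfly Flight-Period Phenometrics from Surveys and Incidental Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates early-season (10%) and mid-season (50%) flight-period
    days-of-year for butterflies from two community-science data streams:
    structured Pollard-style transect counts, via penalized-spline Poisson
    flight curves with site-varying abundance and survey-resampling bootstrap
    confidence intervals, and presence-only incidental occurrence records, via
    empirical quantiles with record-resampling bootstrap intervals. Accumulates
    growing degree days per one-degree grid cell with a single-sine
    approximation between base and upper thresholds, relates phenometrics to
    log growing degree days and overwinter strategy with random-intercept
    linear mixed models selected by AIC (with marginal and conditional
    pseudo-R-squared), and compares the two streams with paired-unit matching,
    a day-0 sanity check, and confidence-interval-width regressions. Includes a
    synthetic-data generator with an analytic truth table for parameter
    recovery and coverage testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    lme4,
    lmerTest,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
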