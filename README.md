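# flightwatch

Butterfly flight-period phenometrics from two community-science data
streams, at the species × 1-degree-grid-cell × year grain:

* **Survey stream** — repeated Pollard-style transect counts (absences
  included). Counts are fit with a penalized-spline Poisson model,
  `count ~ exp{f(DOY) + site}`, assuming phenology is synchronized within
  a grid cell while abundance varies by site; the normalized curve's area
  percentiles give the **10% (early-season)** and **50% (mid-season)**
  days-of-year, with 95% CIs from resampling unique surveys.
* **Incidental stream** — presence-only records (photo platforms).
  After exact-key deduplication (species, date, lon, lat) and a
  10-record unit threshold, phenometrics are empirical DOY quantiles
  (type-7 convention) with record-resampling bootstrap CIs.

Around the two estimators the package provides: growing degree days by
the single-sine method (10/30 °C thresholds, Jan 1–Jun 30 window),
random-intercept mixed models of phenometric DOY on log(GDD), overwinter
strategy and traits (AIC selection, marginal/conditional pseudo-R²), a
"day-0" sanity check against field-guide onset dates, CI-overlap and
CI-width-vs-effort comparisons between streams, and a fully seeded
synthetic-data generator with an analytic truth table (Gaussian-mixture
flight curves per generation) for recovery and calibration testing.

It is aimed at ecologists comparing structured and opportunistic
phenology monitoring, and at methodologists who need a tested, synthetic
ground-truth harness for percentile phenometrics.

## Worked example

```r
library(flightwatch)
library(dplyr)

daily_gdd_single_sine(c(20, 5, 12), c(20, 15, 26))
#> [1] 10.000000  1.591549  9.000000
# a constant 20 C day accumulates 20 - 10 = 10 degree-days; a 5-15 C day
# clips the sine at the 10 C base (amplitude/pi = 1.59)

cells <- tibble(cell_id = cell_id_from_lonlat(c(-85, -85), c(38, 39)),
                lat = c(38, 39))
climate <- generate_climate(cells, 2015:2016, seed = 1)
gdd <- gdd_table(climate)
gdd
#> # A tibble: 4 × 5
#>   cell_id  year   gdd window_start window_end
#> 1 c-85_38  2015  777.            1        181
#> 2 c-85_38  2016  806.            1        182
#> 3 c-85_39  2015  709.            1        181
#> 4 c-85_39  2016  744.            1        182
# the higher-latitude cell is cooler, as the climate generator intends

pool  <- generate_species_pool(6, seed = 2)
truth <- simulate_true_phenology(pool$traits, gdd, pool$coef, seed = 3)
surveys <- simulate_surveys(truth, survey_design(), pool$traits, seed = 4)
occ     <- simulate_incidental(truth, effort_model(), pool$traits, seed = 5)

sp <- survey_phenometrics(surveys, B = 100, seed = 6)
ip <- incidental_phenometrics(occ, B = 300, seed = 7)
pairs <- match_paired_units(sp, ip)
#> paired 48 unit-percentiles (0 survey-only, 0 incidental-only dropped)
head(pairs, 3) |>
  select(species_id, year, percentile,
         doy_estimate_survey, doy_estimate_incidental, ci_overlap)
#>   species_id  year percentile doy_survey doy_incidental ci_overlap
#> 1 sp01        2015         10       181.           183.  TRUE
#> 2 sp01        2015         50       194.           193    TRUE
#> 3 sp01        2016         10       187.           184.  TRUE
# the two streams agree to a few days and their CIs overlap

frame <- build_model_frame(pairs, gdd, pool$traits,
                           percentile = 10, source = "survey")
fit_random_intercept_lmm(frame)
#> Random-intercept LMM (REML), n = 24 obs / 6 species
#> AIC 146.9 | marginal R2 0.879 | conditional R2 0.928
#>   term                    estimate    se    df p_value
#> 1 overwinter_classegg        493.  221.   17.0  0.0390
#> ...
#> 6 log_gdd                    -45.6  33.3  17.0  0.188
# one arrival intercept per overwinter class, plus the log-GDD slope
# (negative: warmer cell-years fly earlier); at 24 units the slope is
# noisy — the acceptance simulations use 300 units per replicate
```

The full pipeline (simulate → GDD → both streams → pairing → models →
comparisons, all artifacts as headered CSV plus a deterministic run log):

```r
res <- run_pipeline(default_config(), out_dir = "flightwatch_run")
```

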