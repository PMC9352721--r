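---
title: "Estimating butterfly flight-period phenometrics from two data streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating butterfly flight-period phenometrics from two data streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adult butterfly flight periods shift with climate, and two very different
kinds of community-science data can track them. Structured monitoring
programs walk fixed transects ("Pollard walks") at regular intervals and
record counts of every species — including zeros, which carry real
information. Incidental platforms (photo-vouchered species reports) produce
far more records over a far wider area, but with no effort control and no
absences. `flightwatch` implements both estimation pathways at a common
spatial grain (1-degree grid cells, species-cell-year units), relates the
resulting phenometrics to accumulated warmth and overwinter biology, and
quantifies how well the cheap, abundant stream reproduces the expensive,
structured one.

The phenometrics are the days-of-year (DOY, 1-based) at which 10% and 50%
of the season's adult activity has occurred — early-season and mid-season
metrics that are less biased by sampling effort than first-appearance
dates.

## Survey stream: penalized-spline flight curves

For an eligible species-cell-year, counts are modeled as

$$y_{sd} \sim \text{Poisson}\!\left(\exp\{f(d) + \gamma_s\}\right),$$

where $f$ is a cubic P-spline smooth in DOY (second-order difference
penalty) and $\gamma_s$ are site fixed effects on the log scale. This
encodes the working assumption that phenology is synchronized within a
cell while local abundance varies by site: after normalizing
$\exp\{\hat f\}$ to unit area, the site effects cancel and the curve is
invariant to rescaling any site's abundance. Fitting uses `mgcv::gam`
(basis dimension 17 by default, smoothness by GCV; both configurable via
`spline_config()`). Percentiles are extracted by trapezoid-rule inversion
of the cumulative curve on a daily grid spanning the unit's observed
season — density outside the sampled range is treated as zero, a
documented truncation.

Eligibility mirrors standard practice for multi-program transect data:
a cell-year needs at least 10 surveys across 3 or more sites; the species
must be detected in at least 4 surveys; and at one or more sites where it
was observed later in the year it must be absent from that site's first
survey (otherwise the flight period may already be underway when the
program starts — many programs are not required to begin until June).
The last rule is why survey tables must contain explicit zero counts.

Confidence intervals resample unique surveys (site-date visits) with
replacement, B = 200 by default, and take the 2.5/97.5 percentile interval
of the re-extracted percentiles. Replicate refits hold the smoothing
parameter at the full-data GCV value and run a penalized IRLS on the basis
and penalty extracted from the full fit, with visit multiplicities as
prior weights — exactly the replicated-row refit at fixed smoothness, at a
small fraction of the cost of re-running GCV per replicate. Replicates
that fail to converge are dropped; if more than half fail, the unit is
flagged and no interval is reported.

## Incidental stream: empirical quantiles

Presence-only records are deduplicated on the literal key (species, date,
longitude, latitude) at full stored precision, assigned to 1-degree cells
by the floor of their coordinates, and a species-cell-year needs at least
10 records. The 10%/50% phenometrics are empirical quantiles of record
DOYs under the linear-interpolation-of-order-statistics convention
(`stats::quantile` type 7; the type is configurable, since no single
convention is canonical). Intervals come from resampling records with
replacement (B = 500 by default; quantiles are cheap relative to spline
refits).

A known limitation, reproduced rather than hidden by our simulations: the
percentile bootstrap is well calibrated for the median but undercovers
tail quantiles at small samples — at n = 30 records the 10% quantile's
nominal 95% interval covers roughly 82–85% of the time. Consumers of
early-season metrics from record-poor units should treat those intervals
as optimistic.

## Growing degree days

Thermal forcing is indexed by growing degree days accumulated from
January 1 to June 30 per cell-year, using the single-sine approximation
with the generic thresholds of 10 °C (base) and 30 °C (upper, horizontal
Baskerville–Emin-style cutoff). The daily value is the analytic integral
of the truncated sine through tmin/tmax; it is bounded in [0, 20] °C·day,
monotone in both temperatures, and verified in the tests against dense
numeric integration to 10⁻³ °C·day. A single-sine needs a daily range, so
the module consumes tmin/tmax directly (gridded daily climate products
supply them); when several sub-cell series share a cell, tmin/tmax are
averaged to cell means *before* the sine computation — a deliberate,
documented order, exposed rather than inferred.

## The mixed model

Matched units (phenometrics estimable from *both* streams) enter a
Gaussian random-intercept model per stream and percentile:

$$\text{DOY}_{i} = \alpha_{\text{stage}(i)} + \beta \log(\text{GDD}_i)
 + \mathbf{x}_i^\top \boldsymbol\delta + u_{\text{species}(i)} +
 \varepsilon_i,$$

with one intercept per overwinter class (egg, larva, pupa, adult diapause,
migrant; no global intercept, so each stage's arrival is directly
interpretable), natural-log GDD, optional trait covariates, and a species
random intercept. Fitting uses `lmerTest::lmer` with
Satterthwaite-approximate p-values (labeled approximate). Candidate models
are compared by AIC on ML fits with ties broken toward fewer parameters,
and the winner is refit by REML for reported coefficients — the standard
split when selecting over fixed effects. Marginal and conditional
pseudo-R² follow the variance-component decomposition
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_u + \sigma^2_\varepsilon)$
and $R^2_c = (\sigma^2_f + \sigma^2_u) / (\cdot)$, with $\sigma^2_f$ the
variance of the fixed-effect linear predictor; the formula is implemented
in `nakagawa_r2()` and cross-checked against its plug-in form in the
tests.

Two degenerate inputs are handled explicitly: a singular fixed design
errors naming the collinear columns, and a constant response (zero
residual variance, outside the mixed-model parameter space) returns a
degenerate fit with all slopes zero rather than an optimizer failure.

## The synthetic world

The generator produces data with the statistical structure the estimators
assume, plus an analytic truth table, so every estimator can be tested for
recovery and calibration:

* **Climate** — sinusoidal annual cycle in daily mean temperature plus a
  per-cell offset (default −1 °C per degree latitude about the regional
  mean, creating a GDD gradient) and Gaussian noise; tmin/tmax are the
  mean ∓ half a diurnal range, so tmin ≤ tmax by construction.
* **Species** — five overwinter classes assigned cyclically (all present
  whenever there are ≥ 5 species), voltinism 1–2, lognormal wing size,
  detectability in (0, 1], and a species random intercept drawn
  N(0, σ²). Default stage intercepts place resident emergence in the
  order adult < pupa < larva < egg with migrants arriving last, and the
  default log-GDD slope is −30 days per log degree-day with species sd 8
  and unit-level sd 10 — the regime the recovery simulations state.
* **Truth** — the first-generation mean DOY is stage intercept + slope ×
  log(GDD) + species intercept + unit noise; later generations follow at
  a fixed gap (60 d), giving a Gaussian-mixture flight curve whose 10%
  and 50% days are computed by numeric inversion of the mixture CDF
  (agreeing with `qnorm` in the univoltine case to the root-finder
  tolerance). Generation weights are configuration, not inference: the
  abundance split across generations of multivoltine species is not
  something the downstream analysis identifies, so the generator exposes
  it and defaults to equal weights.
* **Surveys** — visits at fixed intervals (weekly by default) within a
  program season (default May 1 – Sep 30; a June 1 start reproduces the
  late-start censoring many real programs have), Poisson counts with mean
  site multiplier × seasonal total × curve density × detectability, zeros
  recorded. Seasonal totals are lognormal with a 3× higher median for
  locally common species.
* **Incidental records** — a thinned inhomogeneous point process with
  intensity ∝ curve density × observer effort × detectability, where
  effort is a piecewise-linear seasonal ramp times a weekend multiplier —
  a deliberately minimal two-parameter stand-in for opportunistic
  reporting bias. The default base rate yields ≈ 30 records per unit,
  matching the record density at which incidental phenometrics are
  typically estimable. Coordinates are uniform within the cell; a
  designated confusable species pair can have labels swapped with fixed
  probability (off by default).

What the generator does **not** emulate — and therefore what passing
tests cannot certify about real data: spatial habitat structure within
cells, weather-dependent detection, observer heterogeneity and checklist
structure, range edges, taxonomic reporting bias, and real flight-curve
asymmetry beyond Gaussian mixtures.

## Day-0 check and stream comparison

Every analysis unit is paired across streams by an inner join on
species-cell-year-percentile; unmatched units are counted and logged. The
"day 0" sanity anchor — one week before a species' typical flight
initiation, supplied as an input table of field-guide onset dates (the
pipeline's synthetic runs derive a stand-in from the truth table) — flags
early-season estimates that precede plausible flight. CI overlap between
streams uses closed intervals (touching endpoints overlap: the
conservative convention), and a species is called "persistently earlier"
in the incidental stream only when strictly earlier in every matched unit
with at least three units. CI width is regressed on stream-specific effort
covariates (surveys and sites; record count) plus species confusability.

## Problem sizes and reproducibility

The test suite and acceptance script size their simulations for a single
CPU: 200 units per coverage run (B = 200 survey / 500 incidental), 100
replicates of 300 units for mixed-model recovery, and a demo pipeline of
5 species × 4 cells × 3 years. Every random step takes an explicit seed;
the pipeline derives per-stage seeds from one master seed and writing the
same configuration twice produces byte-identical artifacts (the run log
contains seeds and a configuration hash, no timestamps).

## Known limitations

* Tail-quantile bootstrap undercoverage at small n (above).
* Curve support truncation: density outside a unit's surveyed span is
  zero, so a flight period substantially underway before the first survey
  biases the 10% metric late — this is exactly what the first-survey
  eligibility rule screens against, and the censoring-direction test
  verifies the sign of the residual effect.
* GDD uses cell-mean tmin/tmax; applying the sine per sub-cell series
  before averaging would give slightly different (Jensen-gap) values. The
  order is a config switch with the cell-mean default documented above.
* p-values from the mixed models use approximate degrees of freedom and
  should be read as such; model comparison rests on AIC, not p-values.
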