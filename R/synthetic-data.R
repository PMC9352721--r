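# Synthetic two-stream phenology data with a known truth table.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: within-cell synchronized flight curves with site-varying abundance,
# Pollard-style survey programs whose seasons may start as late as June 1,
# presence-only records thinned by observer effort, and first-generation
# emergence timing driven linearly by log(GDD) and overwinter stage.

#' Default true-model coefficients for the generator
#'
#' Stage-level arrival intercepts (days), the log-GDD slope (days per log
#' degree-day), the species random-intercept sd, the unit-level residual sd,
#' and flight-curve shape parameters. Residents overwintering at more advanced
#' stages emerge earlier (adult < pupa < larva < egg), and migrants arrive
#' last; the slope is negative so warmer cell-years fly earlier.
#'
#' @param stage_intercepts named numeric, one intercept per overwinter class.
#' @param log_gdd_slope slope on natural-log GDD (negative: earlier with
#'   warmth).
#' @param species_sd sd of the species random intercept (days).
#' @param unit_sd sd of unit-level (species-cell-year) noise (days).
#' @param gen_sd within-generation flight-curve sd (days).
#' @param gen_gap days between successive generation means.
#' @param gen_weights optional list of simplex weight vectors indexed by
#'   voltinism; `NULL` means equal weights.
#' @param total_median,total_sdlog,common_mult lognormal seasonal-total
#'   abundance: median for uncommon species, log-sd, and the multiplier
#'   applied to locally common species.
#' @return a list usable as `coef_truth` by the generator functions.
#' @export
default_coef_truth <- function(stage_intercepts = c(egg = 415, larva = 398.8,
                                                    pupa = 382.1, adult = 353.7,
                                                    migrant = 431.9),
                               log_gdd_slope = -30,
                               species_sd = 8,
                               unit_sd = 10,
                               gen_sd = 10,
                               gen_gap = 60,
                               gen_weights = NULL,
                               total_median = 200,
                               total_sdlog = 0.5,
                               common_mult = 3) {
  list(stage_intercepts = stage_intercepts, log_gdd_slope = log_gdd_slope,
       species_sd = species_sd, unit_sd = unit_sd, gen_sd = gen_sd,
       gen_gap = gen_gap, gen_weights = gen_weights,
       total_median = total_median, total_sdlog = total_sdlog,
       common_mult = common_mult)
}

overwinter_classes <- c("egg", "larva", "pupa", "adult", "migrant")

# Gaussian-mixture flight curve: density, CDF and quantile (analytic truth).
mixture_density <- function(x, means, sds, weights) {
  out <- numeric(length(x))
  for (j in seq_along(means)) {
    out <- out + weights[j] * dnorm(x, means[j], sds[j])
  }
  out
}

mixture_cdf <- function(x, means, sds, weights) {
  out <- numeric(length(x))
  for (j in seq_along(means)) {
    out <- out + weights[j] * pnorm(x, means[j], sds[j])
  }
  out
}

#' Quantile of a Gaussian-mixture flight curve
#'
#' Numeric inversion of the mixture CDF by root finding; with a single
#' component this agrees with `qnorm` to the root-finder tolerance.
#'
#' @param p probability in (0, 1).
#' @param means,sds,weights mixture components; weights must sum to 1.
#' @return the day-of-year at which the cumulative curve reaches `p`.
#' @export
mixture_quantile <- function(p, means, sds, weights) {
  stopifnot(length(means) == length(sds), length(means) == length(weights),
            abs(sum(weights) - 1) < 1e-8, p > 0, p < 1)
  lo <- min(means - 8 * sds)
  hi <- max(means + 8 * sds)
  uniroot(function(x) mixture_cdf(x, means, sds, weights) - p,
          lower = lo, upper = hi, tol = 1e-9)$root
}

#' Generate daily synthetic climate for a set of grid cells
#'
#' Daily mean temperature follows a sinusoidal annual cycle plus a per-cell
#' offset and Gaussian noise; tmin/tmax are the mean minus/plus half the
#' diurnal range, so `tmin <= tmax` always holds.
#'
#' @param cells tibble with `cell_id` and optionally `lat` (degrees); when
#'   `cell_offsets` is not supplied and `lat` is present, cooler cells are
#'   produced at higher latitude (-1 degree C per degree latitude about the
#'   regional mean).
#' @param years integer vector of calendar years.
#' @param climate_params list: `annual_mean` (degrees C), `amplitude` (degrees C,
#'   seasonal half-range), `diurnal_range` (> 0), `noise_sd`, `peak_doy`
#'   (warmest day of the cycle), `cell_offsets` (named by cell, optional).
#' @param seed integer seed; the same seed and config give an identical table.
#' @return tibble: `cell_id`, `date`, `tmin`, `tmax`.
#' @export
generate_climate <- function(cells, years,
                             climate_params = list(),
                             seed = 1) {
  stopifnot(length(years) > 0)
  p <- utils::modifyList(
    list(annual_mean = 12, amplitude = 14, diurnal_range = 10,
         noise_sd = 2, peak_doy = 200, cell_offsets = NULL),
    climate_params)
  if (p$diurnal_range <= 0) {
    stop("`diurnal_range` must be positive", call. = FALSE)
  }
  if (is.character(cells)) cells <- tibble::tibble(cell_id = cells)
  assert_columns(cells, "cell_id", "cells")
  offsets <- p$cell_offsets
  if (is.null(offsets)) {
    if ("lat" %in% names(cells)) {
      offsets <- setNames(-(cells$lat - mean(cells$lat)), cells$cell_id)
    } else {
      offsets <- setNames(rep(0, nrow(cells)), cells$cell_id)
    }
  }
  set.seed(seed)
  out <- purrr::map(cells$cell_id, function(cid) {
    purrr::map(sort(unique(as.integer(years))), function(yr) {
      n <- days_in_year(yr)
      doy <- seq_len(n)
      tmean <- p$annual_mean + offsets[[cid]] +
        p$amplitude * cos(2 * pi * (doy - p$peak_doy) / n) +
        rnorm(n, 0, p$noise_sd)
      tibble::tibble(cell_id = cid,
                     date = date_from_doy(yr, doy),
                     tmin = tmean - p$diurnal_range / 2,
                     tmax = tmean + p$diurnal_range / 2)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out
}

#' Generate a species pool with life-history traits and true coefficients
#'
#' Overwinter classes are assigned cyclically so that all five classes (egg,
#' larva, pupa, adult diapause, and migrant) are represented whenever
#' `n_species >= 5`. Species random intercepts are drawn from
#' `N(0, species_sd^2)`.
#'
#' @param n_species number of species (>= 1).
#' @param coef_truth list from [default_coef_truth()]; `species_sd < 0` is
#'   rejected.
#' @param seed integer seed.
#' @return list with `traits` (tibble, one row per species) and `coef`
#'   (the input coefficients plus named `species_effects`).
#' @export
generate_species_pool <- function(n_species, coef_truth = default_coef_truth(),
                                  seed = 1) {
  stopifnot(n_species >= 1)
  if (coef_truth$species_sd < 0) {
    stop("species random-intercept sd must be non-negative", call. = FALSE)
  }
  set.seed(seed)
  ids <- sprintf("sp%02d", seq_len(n_species))
  classes <- rep_len(overwinter_classes, n_species)
  traits <- tibble::tibble(
    species_id = ids,
    overwinter_class = classes,
    voltinism = ifelse(classes == "migrant", 1L,
                       sample(1:2, n_species, replace = TRUE,
                              prob = c(0.7, 0.3))),
    host_breadth = sample(c("specialist", "generalist"), n_species,
                          replace = TRUE),
    locally_common = rbinom(n_species, 1, 0.5),
    wing_size = round(rlnorm(n_species, log(40), 0.3), 1),
    mobility = sample(1:5, n_species, replace = TRUE),
    canopy_assoc = rbinom(n_species, 1, 0.3),
    egg_cluster = rbinom(n_species, 1, 0.2),
    detectability = round(runif(n_species, 0.4, 1), 3),
    confusability = round(runif(n_species, 0, 0.4), 3)
  )
  coef_truth$species_effects <- setNames(
    rnorm(n_species, 0, coef_truth$species_sd), ids)
  list(traits = traits, coef = coef_truth)
}

#' Simulate true flight-period phenology per species-cell-year
#'
#' The first-generation mean day-of-year is the stage intercept plus the
#' log-GDD slope times `log(gdd)` plus the species random intercept plus
#' unit-level Gaussian noise. Later generations (voltinism > 1) follow at
#' fixed gaps, giving a Gaussian-mixture flight curve; the true 10% and 50%
#' days are obtained by analytic/numeric inversion of the mixture CDF.
#' Seasonal total abundance is lognormal with a higher median for locally
#' common species.
#'
#' @param traits species trait tibble from [generate_species_pool()].
#' @param gdd_by_cell_year tibble `cell_id`, `year`, `gdd` (positive).
#' @param coef_truth coefficient list carrying `species_effects` (from
#'   [generate_species_pool()]).
#' @param seed integer seed.
#' @return tibble: unit keys, per-generation `gen_means`/`gen_sds`/
#'   `gen_weights` (list-columns), `seasonal_total`, `true_doy10`,
#'   `true_doy50`. Cell-years with non-positive GDD are skipped with a
#'   warning.
#' @export
simulate_true_phenology <- function(traits, gdd_by_cell_year, coef_truth,
                                    seed = 1) {
  assert_columns(gdd_by_cell_year, c("cell_id", "year", "gdd"),
                 "gdd_by_cell_year")
  if (is.null(coef_truth$species_effects)) {
    stop("coef_truth must carry `species_effects` (use generate_species_pool)",
         call. = FALSE)
  }
  bad <- gdd_by_cell_year$gdd <= 0 | is.na(gdd_by_cell_year$gdd)
  if (any(bad)) {
    warning(sprintf("skipping %d cell-year(s) with missing/non-positive GDD",
                    sum(bad)))
    gdd_by_cell_year <- gdd_by_cell_year[!bad, , drop = FALSE]
  }
  set.seed(seed)
  units <- tidyr::crossing(species_id = traits$species_id,
                           gdd_by_cell_year[, c("cell_id", "year", "gdd")])
  units <- dplyr::left_join(units, traits, by = "species_id")
  ct <- coef_truth
  n <- nrow(units)
  mu1 <- ct$stage_intercepts[units$overwinter_class] +
    ct$log_gdd_slope * log(units$gdd) +
    ct$species_effects[units$species_id] +
    rnorm(n, 0, ct$unit_sd)
  totals <- rlnorm(n,
                   log(ct$total_median) +
                     log(ct$common_mult) * units$locally_common,
                   ct$total_sdlog)
  rows <- purrr::map(seq_len(n), function(i) {
    k <- units$voltinism[i]
    means <- mu1[i] + (seq_len(k) - 1) * ct$gen_gap
    sds <- rep(ct$gen_sd, k)
    w <- if (!is.null(ct$gen_weights) && length(ct$gen_weights) >= k &&
             !is.null(ct$gen_weights[[k]])) {
      ct$gen_weights[[k]]
    } else {
      rep(1 / k, k)
    }
    tibble::tibble(
      species_id = units$species_id[i], cell_id = units$cell_id[i],
      year = units$year[i], gdd = units$gdd[i],
      gen_means = list(means), gen_sds = list(sds), gen_weights = list(w),
      seasonal_total = totals[i],
      true_doy10 = mixture_quantile(0.10, means, sds, w),
      true_doy50 = mixture_quantile(0.50, means, sds, w))
  })
  dplyr::bind_rows(rows)
}

#' Survey design for the synthetic Pollard-style programs
#'
#' @param n_sites_per_cell sites walked per grid cell.
#' @param season_start_doy,season_end_doy survey season bounds (DOY,
#'   program-level; many real programs are not required to start until June,
#'   i.e. DOY 152).
#' @param visit_interval_days days between successive visits.
#' @param site_abundance_multipliers optional positive multipliers, one per
#'   site; `NULL` draws them lognormal(0, 0.5).
#' @return a `survey_design` list, validated.
#' @export
survey_design <- function(n_sites_per_cell = 4,
                          season_start_doy = 121,
                          season_end_doy = 273,
                          visit_interval_days = 7,
                          site_abundance_multipliers = NULL) {
  stopifnot(season_start_doy < season_end_doy, n_sites_per_cell >= 1,
            visit_interval_days >= 1)
  if (!is.null(site_abundance_multipliers) &&
      any(site_abundance_multipliers <= 0)) {
    stop("site abundance multipliers must be positive", call. = FALSE)
  }
  structure(list(n_sites_per_cell = as.integer(n_sites_per_cell),
                 season_start_doy = as.integer(season_start_doy),
                 season_end_doy = as.integer(season_end_doy),
                 visit_interval_days = as.integer(visit_interval_days),
                 site_abundance_multipliers = site_abundance_multipliers),
            class = "survey_design")
}

#' Simulate Pollard-style transect survey counts
#'
#' Visits happen at fixed intervals within the survey season at every site of
#' every cell in the truth table. Counts are Poisson with mean
#' site multiplier x seasonal total x flight-curve density at the visit DOY x
#' detectability. Zero counts are recorded: surveys report absences.
#'
#' @param truth tibble from [simulate_true_phenology()].
#' @param design a [survey_design()].
#' @param traits species trait tibble (for detectability).
#' @param seed integer seed.
#' @return tibble: `site_id`, `date`, `species_id`, `count`, `cell_id`
#'   (plus `year`, `doy` convenience columns).
#' @export
simulate_surveys <- function(truth, design = survey_design(), traits,
                             seed = 1) {
  stopifnot(inherits(design, "survey_design"))
  set.seed(seed)
  det <- setNames(traits$detectability, traits$species_id)
  doys <- seq(design$season_start_doy, design$season_end_doy,
              by = design$visit_interval_days)
  cells <- unique(truth$cell_id)
  mult <- design$site_abundance_multipliers
  sites <- purrr::map(cells, function(cid) {
    m <- mult %||% rlnorm(design$n_sites_per_cell, 0, 0.5)
    m <- rep_len(m, design$n_sites_per_cell)
    tibble::tibble(cell_id = cid,
                   site_id = sprintf("%s_s%02d", cid,
                                     seq_len(design$n_sites_per_cell)),
                   site_mult = m)
  }) |> dplyr::bind_rows()

  out <- purrr::map(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    dens <- mixture_density(doys, tr$gen_means[[1]], tr$gen_sds[[1]],
                            tr$gen_weights[[1]])
    st <- sites[sites$cell_id == tr$cell_id, ]
    grid <- tidyr::crossing(st, doy = doys)
    grid$dens <- rep(dens, times = nrow(st))
    lambda <- grid$site_mult * tr$seasonal_total * grid$dens *
      det[[tr$species_id]]
    tibble::tibble(site_id = grid$site_id,
                   date = date_from_doy(tr$year, grid$doy),
                   species_id = tr$species_id,
                   count = rpois(nrow(grid), lambda),
                   cell_id = tr$cell_id,
                   year = tr$year,
                   doy = grid$doy)
  }) |> dplyr::bind_rows()
  dplyr::arrange(out, .data$species_id, .data$cell_id, .data$year,
                 .data$site_id, .data$doy)
}

#' Observer-effort model for incidental reporting
#'
#' Effort is a piecewise-linear seasonal ramp (rising from `floor` at DOY 1 to
#' 1 at `peak_doy`, flat after) times a weekend multiplier — a two-parameter
#' stand-in for the known bias of opportunistic recording toward summer
#' weekends.
#'
#' @param base_rate expected records per unit at full effort and
#'   detectability 1 (scales the thinned point process).
#' @param ramp_floor effort level on Jan 1 (0 censors the early season hard).
#' @param peak_doy DOY at which the ramp reaches 1.
#' @param weekend_mult multiplier applied on Saturdays and Sundays.
#' @return an `effort_model` list.
#' @export
effort_model <- function(base_rate = 35, ramp_floor = 0.25, peak_doy = 150,
                         weekend_mult = 2) {
  stopifnot(base_rate >= 0, ramp_floor >= 0, weekend_mult >= 0)
  structure(list(base_rate = base_rate, ramp_floor = ramp_floor,
                 peak_doy = peak_doy, weekend_mult = weekend_mult),
            class = "effort_model")
}

effort_weight <- function(model, doy, date) {
  ramp <- pmin(1, model$ramp_floor +
                 (1 - model$ramp_floor) * doy / model$peak_doy)
  ramp <- pmax(0, ramp)
  ramp * ifelse(is_weekend(date), model$weekend_mult, 1)
}

# "c<lon>_<lat>" -> SW corner of the 1-degree tile
cell_bounds <- function(cell_id) {
  m <- regmatches(cell_id, regexec("^c(-?\\d+)_(-?\\d+)$", cell_id))
  bad <- vapply(m, length, 1L) != 3
  if (any(bad)) {
    stop("cell_id not in c<lon>_<lat> form: ", cell_id[bad][1], call. = FALSE)
  }
  tibble::tibble(lon0 = as.numeric(vapply(m, `[`, "", 2)),
                 lat0 = as.numeric(vapply(m, `[`, "", 3)))
}

#' Simulate presence-only incidental occurrence records
#'
#' Records are a thinned inhomogeneous point process: the daily intensity is
#' proportional to flight-curve density x observer effort x detectability.
#' The table is presence-only (no zeros); coordinates are jittered uniformly
#' within the 1-degree cell. Optionally a designated confusable species pair
#' has labels swapped with a fixed probability (misidentification; off by
#' default).
#'
#' @param truth tibble from [simulate_true_phenology()]; `cell_id` must be in
#'   `c<lon>_<lat>` form (see [cell_id_from_lonlat()]) so coordinates can be
#'   drawn.
#' @param effort a [effort_model()]; all-zero effort gives an empty table with
#'   a warning.
#' @param traits species trait tibble.
#' @param seed integer seed.
#' @param confusable_pair optional character(2) of species ids whose labels
#'   swap with probability `swap_prob`.
#' @param swap_prob label-swap probability for the confusable pair.
#' @return tibble: `species_id`, `date`, `lon`, `lat`, `platform`, `cell_id`.
#' @export
simulate_incidental <- function(truth, effort = effort_model(), traits,
                                seed = 1, confusable_pair = NULL,
                                swap_prob = 0) {
  stopifnot(inherits(effort, "effort_model"))
  set.seed(seed)
  det <- setNames(traits$detectability, traits$species_id)
  out <- purrr::map(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    n_days <- days_in_year(tr$year)
    doys <- seq_len(n_days)
    dates <- date_from_doy(tr$year, doys)
    lambda <- effort$base_rate *
      mixture_density(doys, tr$gen_means[[1]], tr$gen_sds[[1]],
                      tr$gen_weights[[1]]) *
      effort_weight(effort, doys, dates) *
      det[[tr$species_id]]
    total <- sum(lambda)
    if (total <= 0) return(NULL)
    n <- rpois(1, total)
    if (n == 0) return(NULL)
    picked <- sample.int(n_days, n, replace = TRUE, prob = lambda)
    b <- cell_bounds(tr$cell_id)
    tibble::tibble(species_id = tr$species_id,
                   date = dates[picked],
                   lon = b$lon0 + runif(n),
                   lat = b$lat0 + runif(n),
                   platform = sample(c("inaturalist", "ebutterfly"), n,
                                     replace = TRUE, prob = c(0.7, 0.3)),
                   cell_id = tr$cell_id)
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0) {
    warning("no incidental records generated (effort or intensity all zero)")
    return(tibble::tibble(species_id = character(), date = as.Date(character()),
                          lon = numeric(), lat = numeric(),
                          platform = character(), cell_id = character()))
  }
  if (!is.null(confusable_pair) && swap_prob > 0) {
    stopifnot(length(confusable_pair) == 2)
    idx <- out$species_id %in% confusable_pair
    swap <- idx & rbinom(nrow(out), 1, swap_prob) == 1
    out$species_id[swap] <- ifelse(out$species_id[swap] == confusable_pair[1],
                                   confusable_pair[2], confusable_pair[1])
  }
  dplyr::arrange(out, .data$species_id, .data$cell_id, .data$date)
}
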