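# Flight curves and percentile phenometrics from structured transect counts.
#
# The estimator assumes phenology is synchronized within a 1-degree grid cell
# but lets local abundance vary across sites: counts are modeled as Poisson
# with a penalized-spline smooth in day-of-year shared across sites plus
# site-level fixed effects, and the normalized exponentiated smooth is the
# flight curve whose area percentiles are the phenometrics.

#' Spline configuration for flight-curve fitting
#'
#' Cubic P-splines with a second-order difference penalty; smoothness chosen
#' by GCV by default, with a fixed smoothing parameter as fallback.
#'
#' @param k basis dimension (upper limit; reduced automatically when a unit
#'   has fewer distinct survey days).
#' @param sp fixed smoothing parameter; `NULL` means GCV selection.
#' @param maxit,epsilon IRLS iteration cap and deviance tolerance.
#' @return a `spline_config` list.
#' @export
spline_config <- function(k = 17, sp = NULL, maxit = 100, epsilon = 1e-8) {
  structure(list(k = k, sp = sp, maxit = maxit, epsilon = epsilon),
            class = "spline_config")
}

#' Select survey units eligible for phenometric estimation
#'
#' A (species, cell, year) unit is retained iff (a) its cell-year has at
#' least `min_surveys` surveys (unique site-date visits) across at least
#' `min_sites` sites; (b) the species was detected in at least
#' `min_detections` surveys across all sites; and (c) at one or more sites
#' where the species was observed later that year, it was absent from that
#' site's first survey of the year — guarding against flight periods already
#' underway when the program starts.
#'
#' @param surveys survey tibble with `site_id`, `date`, `species_id`,
#'   `count`, `cell_id`; absence rows (count 0) must be present, otherwise
#'   rule (c) is untestable and an error is thrown.
#' @param min_surveys,min_sites,min_detections the three thresholds.
#' @return tibble of eligible units: `species_id`, `cell_id`, `year`, with
#'   cell-year effort columns `n_surveys`, `n_sites` and the species'
#'   `n_positive_surveys`.
#' @export
filter_survey_units <- function(surveys, min_surveys = 10, min_sites = 3,
                                min_detections = 4) {
  assert_columns(surveys, c("site_id", "date", "species_id", "count",
                            "cell_id"), "surveys")
  if (!any(surveys$count == 0)) {
    stop(paste("survey table has no absence (count 0) rows;",
               "first-survey screening is untestable without them"),
         call. = FALSE)
  }
  surveys <- dplyr::mutate(surveys, date = as.Date(.data$date),
                           year = year_of(.data$date))

  cell_year <- surveys |>
    dplyr::distinct(.data$cell_id, .data$year, .data$site_id, .data$date) |>
    dplyr::group_by(.data$cell_id, .data$year) |>
    dplyr::summarise(n_surveys = dplyr::n(),
                     n_sites = dplyr::n_distinct(.data$site_id),
                     .groups = "drop") |>
    dplyr::filter(.data$n_surveys >= min_surveys, .data$n_sites >= min_sites)

  detections <- surveys |>
    dplyr::group_by(.data$species_id, .data$cell_id, .data$year) |>
    dplyr::summarise(n_positive_surveys = sum(.data$count > 0),
                     .groups = "drop") |>
    dplyr::filter(.data$n_positive_surveys >= min_detections)

  # rule (c): per site-year, first survey of the year must miss the species
  # at >= 1 site where it was subsequently observed
  first_visit <- surveys |>
    dplyr::group_by(.data$species_id, .data$cell_id, .data$year,
                    .data$site_id) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::summarise(seen_at_site = any(.data$count > 0),
                     absent_first = .data$count[1] == 0 &
                       any(.data$count[-1] > 0),
                     .groups = "drop")
  rule_c <- first_visit |>
    dplyr::group_by(.data$species_id, .data$cell_id, .data$year) |>
    dplyr::summarise(passes_first_survey_rule = any(.data$absent_first),
                     .groups = "drop") |>
    dplyr::filter(.data$passes_first_survey_rule)

  detections |>
    dplyr::inner_join(cell_year, by = c("cell_id", "year")) |>
    dplyr::inner_join(rule_c[, c("species_id", "cell_id", "year")],
                      by = c("species_id", "cell_id", "year")) |>
    dplyr::select("species_id", "cell_id", "year", "n_surveys", "n_sites",
                  "n_positive_surveys") |>
    dplyr::arrange(.data$species_id, .data$cell_id, .data$year)
}

#' Fit a normalized flight curve to one unit's survey counts
#'
#' Poisson log-link fit of count on a penalized B-spline basis in day-of-year
#' plus additive (log-scale) site effects, via [mgcv::gam()]. The returned
#' density is the exponentiated smooth evaluated on a daily DOY grid from the
#' unit's first to last survey day, normalized to unit area (trapezoid rule);
#' site effects cancel in the normalization, so the curve is invariant to
#' rescaling any site's abundance. Deterministic given data and config.
#'
#' @param unit_surveys rows of one (species, cell, year) unit, with `doy`
#'   or `date`, `site_id`, `count`. Sites with all-zero totals drop out of
#'   the fit.
#' @param config a [spline_config()].
#' @return a `flight_curve` list: unit keys, `doy_grid`, `density`,
#'   `cumulative`. Errors on all-zero counts; degenerate units whose
#'   detections fall on a single day return an exact point mass there.
#' @export
fit_flight_curve <- function(unit_surveys, config = spline_config()) {
  stopifnot(inherits(config, "spline_config"))
  assert_columns(unit_surveys, c("site_id", "count"), "unit_surveys")
  if (!"doy" %in% names(unit_surveys)) {
    unit_surveys$doy <- doy_of(unit_surveys$date)
  }
  if (all(unit_surveys$count == 0)) {
    stop("all counts are zero; no flight curve to estimate", call. = FALSE)
  }
  col1 <- function(nm, default) {
    if (nm %in% names(unit_surveys)) unit_surveys[[nm]][1] else default
  }
  keys <- list(species_id = col1("species_id", NA_character_),
               cell_id = col1("cell_id", NA_character_),
               year = if ("year" %in% names(unit_surveys)) {
                 unit_surveys$year[1]
               } else if ("date" %in% names(unit_surveys)) {
                 year_of(unit_surveys$date[1])
               } else NA_integer_)

  pos_doys <- unique(unit_surveys$doy[unit_surveys$count > 0])
  grid <- seq(min(unit_surveys$doy), max(unit_surveys$doy))
  if (length(pos_doys) == 1) {
    # exact point mass: every detection on one day
    density <- as.numeric(grid == pos_doys)
    cumulative <- as.numeric(grid >= pos_doys)
    return(structure(c(keys, list(doy_grid = grid, density = density,
                                  cumulative = cumulative,
                                  point_mass = pos_doys)),
                     class = "flight_curve"))
  }

  # sites with zero totals carry no information about this unit's curve
  site_tot <- tapply(unit_surveys$count, unit_surveys$site_id, sum)
  keep <- names(site_tot)[site_tot > 0]
  dat <- unit_surveys[unit_surveys$site_id %in% keep, , drop = FALSE]
  dat$site_id <- factor(dat$site_id)

  k_eff <- max(5, min(config$k, length(unique(dat$doy)) - 1))
  form <- if (nlevels(dat$site_id) > 1) {
    count ~ s(doy, bs = "ps", k = k_eff, m = c(2, 2)) + site_id
  } else {
    count ~ s(doy, bs = "ps", k = k_eff, m = c(2, 2))
  }
  # convergence is checked via fit$converged below; mgcv's step warnings on
  # sparse bootstrap resamples would otherwise flood the bootstrap loop
  fit <- suppressWarnings(
    mgcv::gam(form, family = stats::poisson(), data = dat,
              sp = config$sp,
              control = mgcv::gam.control(maxit = config$maxit,
                                          epsilon = config$epsilon)))
  if (!fit$converged) {
    stop("flight-curve fit did not converge", call. = FALSE)
  }
  nd <- data.frame(doy = grid, site_id = factor(levels(dat$site_id)[1],
                                                levels = levels(dat$site_id)))
  mu <- as.numeric(predict(fit, newdata = nd, type = "response"))
  sp_used <- as.numeric(fit$sp)
  fit_obj <- if (isTRUE(config$keep_fit)) list(fit = fit, data = dat) else NULL
  area <- sum((mu[-1] + mu[-length(mu)]) / 2)  # trapezoid, daily grid
  if (!is.finite(area) || area <= 0) {
    stop("flight-curve fit produced a degenerate density", call. = FALSE)
  }
  density <- mu / area
  cum <- c(0, cumsum((density[-1] + density[-length(density)]) / 2))
  structure(c(keys, list(doy_grid = grid, density = density,
                         cumulative = cum / cum[length(cum)],
                         point_mass = NULL, sp = sp_used,
                         gam = fit_obj)),
            class = "flight_curve")
}

#' Day-of-year at which a flight curve reaches an area percentile
#'
#' Inverts the curve's cumulative area by linear interpolation between grid
#' days; the result is a real DOY (rounding, if wanted, is presentational).
#' Monotone in `p`.
#'
#' @param curve a `flight_curve` from [fit_flight_curve()].
#' @param p percentile in (0, 100), typically 10 or 50.
#' @return real day-of-year.
#' @export
percentile_from_curve <- function(curve, p) {
  stopifnot(inherits(curve, "flight_curve"), p > 0, p < 100)
  if (!is.null(curve$point_mass)) return(as.numeric(curve$point_mass))
  invert_cumulative(curve$doy_grid, curve$cumulative, p / 100)
}

invert_cumulative <- function(grid, cum, target) {
  i <- which(cum >= target)[1]
  if (is.na(i)) return(grid[length(grid)])
  if (i == 1) return(grid[1])
  grid[i - 1] + (target - cum[i - 1]) / (cum[i] - cum[i - 1]) *
    (grid[i] - grid[i - 1])
}

# one weighted penalized-Poisson IRLS refit on a fixed basis: equivalent to
# refitting the spline on replicated rows (weights = visit multiplicities)
# with the smoothing parameter held fixed
pirls_poisson <- function(X, y, w, pen, beta0, maxit = 100, eps = 1e-8) {
  if (sum(w * y) <= 0) return(NULL)
  clamp <- function(e) pmax(pmin(e, 30), -30)
  # penalized deviance (the IRLS objective; eta clamped keeps it finite)
  pdev <- function(beta) {
    eta <- clamp(drop(X %*% beta))
    mu <- exp(eta)
    2 * sum(w * (ifelse(y > 0, y * (log(y) - eta), 0) - (y - mu))) +
      drop(crossprod(beta, pen %*% beta))
  }
  beta <- beta0
  dev_old <- pdev(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- clamp(drop(X %*% beta))
    mu <- exp(eta)
    wm <- w * mu
    z <- eta + (y - mu) / mu
    H <- crossprod(X, wm * X) + pen
    diag(H) <- diag(H) + 1e-7 * mean(diag(H))
    beta_new <- tryCatch(drop(solve(H, crossprod(X, wm * z))),
                         error = function(e) NULL)
    if (is.null(beta_new)) return(NULL)
    # step-halve until the penalized deviance stops increasing
    delta <- beta_new - beta
    step <- 1
    dev <- pdev(beta + delta)
    while ((!is.finite(dev) || dev > dev_old + 1e-10) && step > 1e-10) {
      step <- step / 2
      dev <- pdev(beta + step * delta)
    }
    if (!is.finite(dev) || dev > dev_old + 1e-10) return(NULL)
    beta <- beta + step * delta
    if (abs(dev - dev_old) < eps * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged) return(NULL)
  beta
}

#' Bootstrap phenometric for one survey unit
#'
#' Resamples unique surveys (site-date visits) with replacement, refits the
#' flight curve and re-extracts the percentile per resample; the confidence
#' interval is the percentile interval of the bootstrap distribution and the
#' point estimate comes from the full-data fit. Resamples are refit with the
#' smoothing parameter held at the full-data GCV value (bootstrapping
#' conditional on the smoothness), which keeps replicates comparable and
#' avoids re-running the GCV search per resample.
#'
#' @param unit_surveys one unit's survey rows (zeros included).
#' @param p percentiles to extract (vector, e.g. `c(10, 50)`).
#' @param B bootstrap replicates (>= 2).
#' @param seed integer seed (required for reproducibility).
#' @param level confidence level.
#' @param config a [spline_config()].
#' @return tibble with one row per percentile: unit keys, `source`
#'   (`"survey"`), `percentile`, `doy_estimate`, `ci_low`, `ci_high`,
#'   `ci_width`, `n_surveys`, `n_sites`, `n_positive_surveys`. If more than
#'   half the resamples fail to refit, the CI columns are `NA` and
#'   `ci_failed` is `TRUE`.
#' @export
bootstrap_survey_phenometric <- function(unit_surveys, p = c(10, 50), B = 200,
                                         seed = 1, level = 0.95,
                                         config = spline_config()) {
  stopifnot(B >= 2)
  if (!"doy" %in% names(unit_surveys)) {
    unit_surveys$doy <- doy_of(unit_surveys$date)
  }
  fit_config <- config
  fit_config$keep_fit <- TRUE
  full <- fit_flight_curve(unit_surveys, fit_config)
  est <- vapply(p, function(pp) percentile_from_curve(full, pp), 0)

  visits <- dplyr::distinct(unit_surveys[, c("site_id", "doy")])
  nv <- nrow(visits)
  vkey <- paste(visits$site_id, visits$doy)
  set.seed(seed)
  boot <- matrix(NA_real_, nrow = B, ncol = length(p))

  if (is.null(full$gam)) {
    # point-mass unit: any resample retaining a detection reproduces it
    pos <- unit_surveys[unit_surveys$count > 0, c("site_id", "doy")]
    pos_key <- paste(pos$site_id, pos$doy)
    for (b in seq_len(B)) {
      idx <- sample.int(nv, nv, replace = TRUE)
      if (any(vkey[idx] %in% pos_key)) {
        boot[b, ] <- rep(full$point_mass, length(p))
      }
    }
  } else {
    # weighted penalized-IRLS refits on the full fit's basis and smoothing
    # parameter: exactly the replicated-row refit, without re-running GCV
    fit <- full$gam$fit
    dat <- full$gam$data
    X <- predict(fit, type = "lpmatrix")
    y <- dat$count
    pen <- matrix(0, ncol(X), ncol(X))
    if (length(fit$smooth) > 0) {
      sm <- fit$smooth[[1]]
      ii <- sm$first.para:sm$last.para
      pen[ii, ii] <- fit$sp[1] * sm$S[[1]]
    }
    nd <- data.frame(doy = full$doy_grid,
                     site_id = factor(levels(dat$site_id)[1],
                                      levels = levels(dat$site_id)))
    Xp <- predict(fit, newdata = nd, type = "lpmatrix")
    fkey <- paste(dat$site_id, dat$doy)
    beta0 <- coef(fit)
    for (b in seq_len(B)) {
      idx <- sample.int(nv, nv, replace = TRUE)
      mult <- tabulate(idx, nbins = nv)
      w <- mult[match(fkey, vkey)]
      beta <- pirls_poisson(X, y, w, pen, beta0)
      if (is.null(beta)) next
      mu <- exp(pmin(drop(Xp %*% beta), 30))
      area <- sum((mu[-1] + mu[-length(mu)]) / 2)
      if (!is.finite(area) || area <= 0) next
      cum <- c(0, cumsum((mu[-1] + mu[-length(mu)]) / 2)) / area
      boot[b, ] <- vapply(p, function(pp)
        invert_cumulative(full$doy_grid, cum, pp / 100), 0)
    }
  }
  ok <- stats::complete.cases(boot)
  failed <- mean(!ok) > 0.5
  alpha <- (1 - level) / 2
  ci <- if (failed) {
    matrix(NA_real_, 2, length(p))
  } else {
    apply(boot[ok, , drop = FALSE], 2, quantile,
          probs = c(alpha, 1 - alpha), names = FALSE)
  }
  tibble::tibble(
    species_id = full$species_id, cell_id = full$cell_id, year = full$year,
    source = "survey", percentile = as.numeric(p),
    doy_estimate = est, ci_low = ci[1, ], ci_high = ci[2, ],
    ci_width = ci[2, ] - ci[1, ],
    n_surveys = nv,
    n_sites = dplyr::n_distinct(unit_surveys$site_id),
    n_positive_surveys = nrow(
      dplyr::distinct(unit_surveys[unit_surveys$count > 0,
                                   c("site_id", "doy")])),
    ci_failed = failed)
}

#' Survey-stream phenometrics for every eligible unit
#'
#' Applies [filter_survey_units()], then fits and bootstraps each eligible
#' unit. Units whose full-data fit fails are skipped with a message.
#'
#' @param surveys full survey table.
#' @param percentiles percentiles to extract.
#' @param B,level,config bootstrap and spline settings.
#' @param seed integer seed; per-unit seeds are derived from it.
#' @param min_surveys,min_sites,min_detections passed to
#'   [filter_survey_units()].
#' @return tibble of phenometrics (one row per unit x percentile).
#' @export
survey_phenometrics <- function(surveys, percentiles = c(10, 50), B = 200,
                                seed = 1, level = 0.95,
                                config = spline_config(),
                                min_surveys = 10, min_sites = 3,
                                min_detections = 4) {
  surveys <- dplyr::mutate(surveys, date = as.Date(.data$date),
                           year = year_of(.data$date),
                           doy = doy_of(.data$date))
  units <- filter_survey_units(surveys, min_surveys, min_sites,
                               min_detections)
  if (nrow(units) == 0) {
    message("no survey units pass the eligibility filters")
    return(tibble::tibble())
  }
  out <- purrr::map(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    dat <- surveys[surveys$species_id == u$species_id &
                     surveys$cell_id == u$cell_id &
                     surveys$year == u$year, , drop = FALSE]
    tryCatch(
      bootstrap_survey_phenometric(dat, p = percentiles, B = B,
                                   seed = seed + i, level = level,
                                   config = config),
      error = function(e) {
        message(sprintf("unit %s/%s/%d skipped: %s", u$species_id, u$cell_id,
                        u$year, conditionMessage(e)))
        NULL
      })
  }) |> dplyr::bind_rows()
  out
}
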