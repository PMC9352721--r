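# The synthetic-data generator: climate, species pool, analytic truth, and
# the two observation processes.

test_that("constant forcing gives a flat tmin/tmax climate", {
  cl <- generate_climate(tibble::tibble(cell_id = "cellA"), 2015,
                         list(annual_mean = 20, amplitude = 0,
                              diurnal_range = 10, noise_sd = 0),
                         seed = 1)
  expect_equal(nrow(cl), 365)
  expect_true(all(cl$tmin == 15))
  expect_true(all(cl$tmax == 25))
})

test_that("climate generation is deterministic and rejects bad ranges", {
  cells <- tibble::tibble(cell_id = c("a", "b"))
  a <- generate_climate(cells, 2015:2016, seed = 1)
  b <- generate_climate(cells, 2015:2016, seed = 1)
  expect_identical(a, b)
  expect_gt(nrow(dplyr::anti_join(a, generate_climate(cells, 2015:2016,
                                                      seed = 2),
                                  by = names(a))), 0)
  expect_error(generate_climate(cells, 2015,
                                list(diurnal_range = 0), seed = 1),
               "diurnal_range")
})

test_that("noiseless sinusoid peaks on the annual-cycle peak day", {
  cl <- generate_climate(tibble::tibble(cell_id = "a"), 2015,
                         list(annual_mean = 10, amplitude = 15,
                              noise_sd = 0, peak_doy = 200), seed = 1)
  expect_equal(which.max(cl$tmax), 200)
  expect_true(all(cl$tmin <= cl$tmax))
})

test_that("species pool covers all overwinter classes and respects truth", {
  pool <- generate_species_pool(5, seed = 3)
  expect_setequal(pool$traits$overwinter_class,
                  c("egg", "larva", "pupa", "adult", "migrant"))

  big <- generate_species_pool(40, seed = 3)
  expect_equal(dplyr::n_distinct(big$traits$species_id), 40)
  expect_true(all(big$traits$detectability > 0))

  degen <- generate_species_pool(8, default_coef_truth(species_sd = 0),
                                 seed = 3)
  expect_true(all(degen$coef$species_effects == 0))

  expect_error(generate_species_pool(5, default_coef_truth(species_sd = -1)),
               "non-negative")
})

test_that("true first-generation timing follows the stage/log-GDD model", {
  pool <- generate_species_pool(1, default_coef_truth(
    species_sd = 0, unit_sd = 0, log_gdd_slope = -30), seed = 4)
  gdd <- tibble::tibble(cell_id = c("c-85_38", "c-85_38"),
                        year = c(2015, 2016), gdd = c(800, 1600))
  truth <- simulate_true_phenology(pool$traits, gdd, pool$coef, seed = 4)
  # doubling GDD shifts the whole curve earlier by slope * ln 2
  expect_equal(truth$true_doy50[1] - truth$true_doy50[2], 30 * log(2),
               tolerance = 1e-6)
  intercept <- pool$coef$stage_intercepts[[pool$traits$overwinter_class]]
  expect_equal(truth$true_doy50[1], intercept - 30 * log(800),
               tolerance = 1e-6)
})

test_that("analytic truth quantiles match the normal/mixture oracles", {
  # univoltine Gaussian(180, 10)
  expect_equal(mixture_quantile(0.5, 180, 10, 1), 180, tolerance = 1e-6)
  expect_equal(mixture_quantile(0.1, 180, 10, 1), qnorm(0.1, 180, 10),
               tolerance = 1e-6)
  # well-separated equal mixture: the median falls in the inter-peak gap
  q50 <- mixture_quantile(0.5, c(150, 230), c(5, 5), c(0.5, 0.5))
  expect_gt(q50, 150 + 15)
  expect_lt(q50, 230 - 15)
  # numeric-inversion agreement on random mixtures
  set.seed(5)
  for (i in 1:20) {
    k <- sample(1:3, 1)
    means <- sort(runif(k, 120, 260))
    sds <- runif(k, 4, 15)
    w <- runif(k); w <- w / sum(w)
    for (p in c(0.1, 0.5)) {
      q <- mixture_quantile(p, means, sds, w)
      grid <- seq(min(means) - 80, max(means) + 80, by = 0.001)
      cdf <- sapply(seq_along(means), function(j)
        w[j] * pnorm(grid, means[j], sds[j]))
      brute <- grid[which(rowSums(cdf) >= p)[1]]
      expect_lt(abs(q - brute), 0.01)
    }
  }
})

test_that("true_doy10 <= true_doy50 across a generated world", {
  w <- demo_world()
  expect_true(all(w$truth$true_doy10 <= w$truth$true_doy50))
  expect_equal(vapply(w$truth$gen_weights, sum, 0),
               rep(1, nrow(w$truth)))
  # generation count equals voltinism
  volt <- w$pool$traits$voltinism[match(w$truth$species_id,
                                        w$pool$traits$species_id)]
  expect_equal(lengths(w$truth$gen_means), volt)
})

test_that("cell-years with non-positive GDD are skipped with a warning", {
  pool <- generate_species_pool(2, seed = 6)
  gdd <- tibble::tibble(cell_id = c("a", "b"), year = 2015, gdd = c(900, 0))
  expect_warning(truth <- simulate_true_phenology(pool$traits, gdd,
                                                  pool$coef, seed = 6),
                 "non-positive")
  expect_setequal(unique(truth$cell_id), "a")
})

test_that("surveys record absences, fixed-interval visits, season bounds", {
  sv <- toy_unit_surveys(seed = 21)
  expect_true(any(sv$count == 0))
  expect_true(all(sv$doy >= 121 & sv$doy <= 273))
  expect_equal(sort(unique(diff(sort(unique(sv$doy))))), 7)

  # detectability -> 0: all counts zero but rows remain
  sv0 <- toy_unit_surveys(seed = 21, detectability = 1e-12)
  expect_equal(nrow(sv0), nrow(sv))
  expect_true(all(sv0$count == 0))

  # June 1 program start: no survey precedes first flight of a late flyer
  svj <- toy_unit_surveys(mu = 180, seed = 22, start = 152)
  expect_gte(min(svj$doy), 152)
})

test_that("site abundance multipliers drive pooled count ratios", {
  truth <- gaussian_truth(total = 20000)
  des <- survey_design(n_sites_per_cell = 2, visit_interval_days = 2,
                       site_abundance_multipliers = c(3, 1))
  sv <- simulate_surveys(truth, des, one_species_traits(1), seed = 23)
  tot <- tapply(sv$count, sv$site_id, sum)
  expect_equal(unname(tot[1] / tot[2]), 3, tolerance = 0.05)
})

test_that("incidental records are presence-only, thinned by effort", {
  truth <- gaussian_truth(mu = 200, total = 300)
  tr <- one_species_traits(1)
  occ <- simulate_incidental(truth, effort_model(base_rate = 500),
                             tr, seed = 24)
  expect_false(any(duplicated(names(occ))))
  expect_true(all(occ$lon >= -85 & occ$lon < -84))
  expect_true(all(occ$lat >= 38 & occ$lat < 39))
  expect_true(all(occ$cell_id == "c-85_38"))

  # hard censoring: zero effort before the ramp start
  em <- effort_model(base_rate = 500, ramp_floor = 0, peak_doy = 150)
  occ2 <- simulate_incidental(gaussian_truth(mu = 150, sd = 30), em,
                              tr, seed = 25)
  expect_true(all(doy_of(occ2$date) >= 2))  # weight 0 only exactly at doy 0

  # thinning: expected record count scales linearly with the rate
  n1 <- nrow(simulate_incidental(truth, effort_model(base_rate = 100,
                                                     ramp_floor = 1,
                                                     weekend_mult = 1),
                                 tr, seed = 26))
  n4 <- nrow(simulate_incidental(truth, effort_model(base_rate = 400,
                                                     ramp_floor = 1,
                                                     weekend_mult = 1),
                                 tr, seed = 26))
  expect_equal(n4 / n1, 4, tolerance = 0.15)

  # all-zero effort: empty table with warning
  expect_warning(
    none <- simulate_incidental(truth, effort_model(base_rate = 0), tr,
                                seed = 27),
    "no incidental records")
  expect_equal(nrow(none), 0)
})

test_that("flat-effort record DOYs reproduce the flight curve", {
  truth <- gaussian_truth(mu = 180, sd = 10, total = 300)
  em <- effort_model(base_rate = 2000, ramp_floor = 1, weekend_mult = 1)
  occ <- simulate_incidental(truth, em, one_species_traits(1), seed = 28)
  d <- doy_of(occ$date)
  # KS against the true Gaussian (jitter breaks day-grid ties)
  ks <- suppressWarnings(stats::ks.test(d + runif(length(d), -0.5, 0.5),
                                        "pnorm", 180, 10))
  expect_gt(ks$p.value, 0.01)
  # empirical quantiles converge to analytic truth at n ~ 10,000
  n10k <- simulate_incidental(gaussian_truth(mu = 180, sd = 10,
                                             total = 300),
                              effort_model(base_rate = 10000 / 0.9987,
                                           ramp_floor = 1,
                                           weekend_mult = 1),
                              one_species_traits(1), seed = 29)
  dd <- doy_of(n10k$date)
  expect_gt(length(dd), 5000)
  expect_lt(abs(quantile(dd, 0.1, names = FALSE) - truth$true_doy10), 1)
  expect_lt(abs(quantile(dd, 0.5, names = FALSE) - truth$true_doy50), 1)
})

test_that("generators are reproducible under a fixed seed", {
  w <- demo_world()
  tr2 <- simulate_true_phenology(w$pool$traits, w$gdd, w$pool$coef,
                                 seed = 13)
  expect_identical(w$truth, tr2)
  des <- survey_design()
  expect_identical(simulate_surveys(w$truth, des, w$pool$traits, seed = 14),
                   simulate_surveys(w$truth, des, w$pool$traits, seed = 14))
  expect_identical(
    simulate_incidental(w$truth, effort_model(), w$pool$traits, seed = 15),
    simulate_incidental(w$truth, effort_model(), w$pool$traits, seed = 15))
})

test_that("confusable-pair label swap only touches the designated pair", {
  w <- demo_world()
  occ <- simulate_incidental(w$truth, effort_model(), w$pool$traits,
                             seed = 16, confusable_pair = c("sp01", "sp02"),
                             swap_prob = 1)
  base <- simulate_incidental(w$truth, effort_model(), w$pool$traits,
                              seed = 16)
  tab_base <- table(base$species_id)
  tab_swap <- table(occ$species_id)
  expect_equal(unname(tab_swap["sp01"]), unname(tab_base["sp02"]))
  others <- setdiff(names(tab_base), c("sp01", "sp02"))
  expect_equal(tab_swap[others], tab_base[others])
})
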