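# Shared fixture builders: all synthetic, generated in code at test time.

# single-species Gaussian truth row (the workhorse unit for recovery tests)
gaussian_truth <- function(mu = 180, sd = 10, total = 300,
                           species_id = "sp01", cell_id = "c-85_38",
                           year = 2015) {
  tibble::tibble(species_id = species_id, cell_id = cell_id, year = year,
                 gen_means = list(mu), gen_sds = list(sd),
                 gen_weights = list(1), seasonal_total = total,
                 true_doy10 = qnorm(0.1, mu, sd), true_doy50 = mu)
}

one_species_traits <- function(detectability = 0.8, species_id = "sp01") {
  tibble::tibble(species_id = species_id, detectability = detectability,
                 confusability = 0.1)
}

# cell-year of weekly visits at 3 sites with one focal species; counts
# Poisson around a Gaussian flight curve
toy_unit_surveys <- function(mu = 180, sd = 10, total = 300, seed = 42,
                             n_sites = 3, start = 121, end = 273,
                             interval = 7, detectability = 0.8) {
  truth <- gaussian_truth(mu, sd, total)
  des <- survey_design(n_sites_per_cell = n_sites, season_start_doy = start,
                       season_end_doy = end, visit_interval_days = interval)
  simulate_surveys(truth, des, one_species_traits(detectability), seed = seed)
}

# hand-built survey table exercising the eligibility thresholds: absences
# included, dates within one cell-year
manual_surveys <- function(sites, doys, counts, species = "spA",
                           cell = "c-85_38", year = 2015) {
  tibble::tibble(site_id = sites,
                 date = as.Date(sprintf("%d-01-01", year)) + (doys - 1),
                 species_id = species, count = counts, cell_id = cell)
}

# model frame with known fixed/random structure for LMM recovery tests
sim_frame <- function(n_species = 20, n_units = 300, beta_gdd = -30,
                      sigma_alpha = 8, sigma_eps = 10, seed = 1,
                      stage_int = c(egg = 415, larva = 398.8, pupa = 382.1,
                                    adult = 353.7, migrant = 431.9)) {
  set.seed(seed)
  sp <- sprintf("sp%02d", seq_len(n_species))
  cls <- rep_len(names(stage_int), n_species)
  alpha <- rnorm(n_species, 0, sigma_alpha)
  idx <- sample.int(n_species, n_units, replace = TRUE)
  log_gdd <- log(runif(n_units, 600, 1600))
  tibble::tibble(
    species_id = sp[idx],
    overwinter_class = factor(cls[idx], levels = names(stage_int)),
    log_gdd = log_gdd,
    noise_cov = rnorm(n_units),
    response = stage_int[cls[idx]] + beta_gdd * log_gdd + alpha[idx] +
      rnorm(n_units, 0, sigma_eps))
}

demo_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cells <- tibble::tibble(
        cell_id = cell_id_from_lonlat(c(-85, -85), c(38, 39)),
        lat = c(38, 39))
      climate <- generate_climate(cells, 2015:2016, seed = 11)
      gdd <- gdd_table(climate)
      pool <- generate_species_pool(6, seed = 12)
      truth <- simulate_true_phenology(pool$traits, gdd, pool$coef,
                                       seed = 13)
      cache <<- list(cells = cells, climate = climate, gdd = gdd,
                     pool = pool, truth = truth)
    }
    cache
  }
})
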