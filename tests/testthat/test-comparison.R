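# Stream pairing, day-0 sanity check, CI overlap and width analyses, and
# the end-to-end pipeline.

phen_row <- function(species, cell, year, pct, est, lo, hi, source,
                     n_surveys = 20, n_sites = 3, n_records = 15) {
  out <- tibble::tibble(species_id = species, cell_id = cell, year = year,
                        source = source, percentile = pct,
                        doy_estimate = est, ci_low = lo, ci_high = hi,
                        ci_width = hi - lo)
  if (source == "survey") {
    out$n_surveys <- n_surveys
    out$n_sites <- n_sites
  } else {
    out$n_records <- n_records
  }
  out
}

test_that("pairing is an inner join with logged drops", {
  sp <- dplyr::bind_rows(
    phen_row("a", "c1", 2015, 10, 160, 150, 170, "survey"),
    phen_row("a", "c1", 2016, 10, 158, 148, 168, "survey"),
    phen_row("b", "c1", 2015, 10, 180, 170, 190, "survey"),
    phen_row("c", "c1", 2015, 10, 175, 165, 185, "survey"),
    phen_row("d", "c1", 2015, 10, 190, 180, 200, "survey"))
  ip <- dplyr::bind_rows(
    phen_row("a", "c1", 2015, 10, 161, 151, 171, "incidental"),
    phen_row("b", "c1", 2015, 10, 179, 169, 189, "incidental"),
    phen_row("c", "c1", 2015, 10, 174, 164, 184, "incidental"),
    phen_row("e", "c1", 2015, 10, 200, 190, 210, "incidental"))
  expect_message(pairs <- match_paired_units(sp, ip), "3 unit-percentiles")
  expect_equal(nrow(pairs), 3)
  expect_lte(nrow(pairs), min(nrow(sp), nrow(ip)))
  expect_true(all(c("doy_estimate_survey", "doy_estimate_incidental")
                  %in% names(pairs)))

  # duplicate keys within a stream are an error
  expect_error(suppressMessages(match_paired_units(rbind(sp, sp[1, ]), ip)),
               "duplicate")
  # an empty stream warns and yields an empty pairing
  expect_warning(empty <- match_paired_units(sp, ip[0, ]), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("day-0 arithmetic is exact and summaries count early flags", {
  phen <- dplyr::bind_rows(
    phen_row("a", "c1", 2015, 10, 130, 120, 140, "survey"),
    phen_row("a", "c1", 2016, 10, 110, 100, 120, "survey"),
    phen_row("a", "c1", 2015, 50, 170, 160, 180, "survey"))
  refs <- tibble::tibble(species_id = "a", guide_onset_doy = 120)
  lag <- day0_lag(phen, refs)
  expect_equal(nrow(lag), 2)  # percentile-10 rows only
  expect_equal(lag$day0, c(113, 113))
  expect_equal(lag$lag_days, c(17, -3))
  sm <- summarize_day0(phen, refs)
  expect_equal(sm$prop_before_day0, 0.5)
  expect_true(all(sm$prop_before_day0 >= 0 & sm$prop_before_day0 <= 1))

  # units without a reference are skipped with a message
  phen2 <- dplyr::bind_rows(phen,
                            phen_row("zz", "c1", 2015, 10, 150, 140, 160,
                                     "survey"))
  expect_message(day0_lag(phen2, refs), "skipped")
})

test_that("correctly anchored synthetic cohorts rarely precede day 0", {
  w <- demo_world()
  refs <- day0_refs_from_truth(w$truth)
  # estimates = truth: nothing precedes day 0 by construction
  phen <- tibble::tibble(species_id = w$truth$species_id,
                         cell_id = w$truth$cell_id, year = w$truth$year,
                         source = "survey", percentile = 10,
                         doy_estimate = w$truth$true_doy10)
  sm <- summarize_day0(phen, refs)
  expect_equal(sm$n_before_day0, 0)
  # noisy estimates around truth: flagged fraction stays far below half
  set.seed(61)
  noisy <- dplyr::mutate(phen,
                         doy_estimate = .data$doy_estimate + rnorm(nrow(phen),
                                                                   0, 3))
  sm2 <- summarize_day0(noisy, refs)
  expect_lt(sm2$prop_before_day0, 0.3)
})

test_that("CI overlap uses closed intervals and flags persistent earliness", {
  mk_pair <- function(sp, yr, s_est, s_lo, s_hi, i_est, i_lo, i_hi) {
    suppressMessages(match_paired_units(
      phen_row(sp, "c1", yr, 10, s_est, s_lo, s_hi, "survey"),
      phen_row(sp, "c1", yr, 10, i_est, i_lo, i_hi, "incidental")))
  }
  identical_ci <- mk_pair("a", 2015, 160, 150, 170, 160, 150, 170)
  expect_true(identical_ci$ci_overlap)
  disjoint <- mk_pair("a", 2015, 105, 100, 110, 115, 111, 120)
  expect_false(disjoint$ci_overlap)
  touching <- mk_pair("a", 2015, 105, 100, 110, 115, 110, 120)
  expect_true(touching$ci_overlap)  # closed-interval convention

  # persistently earlier needs >= 3 units, all strictly earlier
  pairs <- dplyr::bind_rows(
    mk_pair("a", 2015, 160, 150, 170, 155, 145, 165),
    mk_pair("a", 2016, 162, 152, 172, 158, 148, 168),
    mk_pair("a", 2017, 161, 151, 171, 157, 147, 167),
    mk_pair("b", 2015, 180, 170, 190, 175, 165, 185),
    mk_pair("b", 2016, 181, 171, 191, 184, 174, 194))
  smry <- ci_overlap_summary(pairs)
  expect_equal(smry$persistently_earlier, "a")
  expect_equal(smry$overall$overlap_rate, 1)
  expect_true(all(smry$by_species$n_pairs == c(3, 2)))
})

test_that("streams sharing one truth mostly overlap", {
  w <- demo_world()
  sv <- simulate_surveys(w$truth, survey_design(), w$pool$traits, seed = 62)
  oc <- simulate_incidental(w$truth, effort_model(), w$pool$traits,
                            seed = 63)
  sp <- suppressMessages(survey_phenometrics(sv, B = 60, seed = 64))
  ip <- suppressMessages(incidental_phenometrics(oc, B = 200, seed = 65))
  pairs <- suppressMessages(match_paired_units(sp, ip))
  expect_gt(nrow(pairs), 5)
  smry <- ci_overlap_summary(pairs)
  expect_gt(min(smry$overall$overlap_rate), 0.8)
})

test_that("CI width regressions use stream-specific effort covariates", {
  traits <- tibble::tibble(species_id = c("a", "b"),
                           confusability = c(0.1, 0.3))
  set.seed(66)
  n <- 60
  sp <- tibble::tibble(species_id = rep(c("a", "b"), n / 2),
                       cell_id = "c1", year = 2015, source = "survey",
                       percentile = 10,
                       n_surveys = sample(10:80, n, TRUE),
                       n_sites = sample(3:10, n, TRUE))
  sp$ci_width <- 100 / sqrt(sp$n_surveys) + rnorm(n, 0, 1)
  sp$doy_estimate <- 170
  fit <- ci_width_regression(sp, traits)
  expect_lt(fit$estimate[fit$term == "n_surveys"], 0)
  expect_true(all(c("n_surveys", "n_sites", "confusability") %in% fit$term))

  ip <- tibble::tibble(species_id = rep(c("a", "b"), n / 2),
                       cell_id = "c1", year = 2015, source = "incidental",
                       percentile = 50,
                       n_records = sample(10:200, n, TRUE))
  ip$ci_width <- 120 / sqrt(ip$n_records) + rnorm(n, 0, 1)
  fiti <- ci_width_regression(ip, traits)
  expect_lt(fiti$estimate[fiti$term == "n_records"], 0)

  # constant widths: degenerate fit, zero slopes, warning
  flat <- dplyr::mutate(ip, ci_width = 12)
  expect_warning(f0 <- ci_width_regression(flat, traits), "degenerate")
  expect_true(all(f0$estimate == 0))
})

test_that("the pipeline runs end to end on a small configuration", {
  cfg <- default_config()
  cfg$simulate$n_species <- 4
  cfg$simulate$lons <- -85
  cfg$simulate$years <- 2015:2016
  cfg$bootstrap <- list(B_survey = 20, B_incidental = 60)
  out1 <- withr::local_tempdir()
  res <- suppressMessages(run_pipeline(cfg, out_dir = out1))
  files <- list.files(out1)
  expect_true(all(c("climate.csv", "traits.csv", "truth.csv", "gdd.csv",
                    "surveys.csv", "occurrences.csv",
                    "phenometrics_survey.csv",
                    "phenometrics_incidental.csv", "paired_units.csv",
                    "run_log.txt") %in% files))
  for (f in setdiff(files, "run_log.txt")) {
    expect_gt(file.size(file.path(out1, f)), 0)
  }
  expect_true(all(res$truth$true_doy10 <= res$truth$true_doy50))
  expect_lte(nrow(res$pairs),
             min(nrow(res$survey_phenometrics),
                 nrow(res$incidental_phenometrics)))
})

test_that("YAML configs round-trip into the pipeline config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 7", "simulate:", "  n_species: 3"), path)
  cfg <- read_config(path)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$simulate$n_species, 3)
  expect_equal(cfg$thresholds$min_surveys, 10)  # defaults merged in
})
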