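test_that("n_persons = 0 yields four empty tables with correct schemas", {
  tabs <- simulate_cohort(sim_config(n_persons = 0))
  expect_identical(nrow(tabs$persons), 0L)
  expect_identical(nrow(tabs$lab_tests), 0L)
  expect_identical(nrow(tabs$dispensations), 0L)
  expect_identical(nrow(tabs$outcomes), 0L)
  expect_named(tabs$lab_tests, c("person_id", "date", "analyte", "value",
                                 "unit", "category"))
  expect_named(tabs$outcomes, c("person_id", "krt_date", "death_date",
                                "emigration_date"))
})

test_that("identical config and seed give identical cohorts", {
  cfg <- sim_config(n_persons = 500, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  for (nm in c("persons", "lab_tests", "dispensations", "outcomes")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  # and the caller's RNG state is untouched
  set.seed(5)
  before <- .Random.seed
  invisible(simulate_cohort(cfg))
  expect_identical(.Random.seed, before)
})

test_that("invalid config fields are rejected by name", {
  expect_error(sim_config(n_persons = -1), "n_persons")
  expect_error(sim_config(10, male_frac = 1.2), "male_frac")
  expect_error(sim_config(10, dipstick_frac = 0.7, pcr_frac = 0.5),
               "pcr_frac")
  expect_error(sim_config(10, krt_baseline_rates = -0.1), "krt_baseline")
  expect_error(sim_config(10, krt_lp_coeffs = 1:3), "krt_lp_coeffs")
  expect_error(sim_config(10, seed = 2^31), "seed")
})

test_that("competing exponentials: symmetry, null cause, closed form", {
  cfg <- sim_config(n_persons = 1,
                    krt_baseline_rates = 0.05, krt_baseline_breaks = numeric(0),
                    death_baseline_rates = 0.05,
                    death_baseline_breaks = numeric(0))
  set.seed(21)
  et <- simulate_event_times(rep(0, 50000), rep(0, 50000), cfg)
  expect_equal(mean(et$cause == "krt"), 0.5, tolerance = 0.015)

  cfg0 <- sim_config(n_persons = 1,
                     krt_baseline_rates = 0, krt_baseline_breaks = numeric(0),
                     death_baseline_rates = 0.05,
                     death_baseline_breaks = numeric(0))
  set.seed(22)
  et0 <- simulate_event_times(rep(0, 5000), rep(0, 5000), cfg0)
  expect_true(all(et0$cause == "death"))

  cfg2 <- sim_config(n_persons = 1,
                     krt_baseline_rates = 0.02, krt_baseline_breaks = numeric(0),
                     death_baseline_rates = 0.08,
                     death_baseline_breaks = numeric(0))
  set.seed(23)
  et2 <- simulate_event_times(rep(0, 100000), rep(0, 100000), cfg2)
  # lifetime P(cause krt) = 0.02 / 0.10 = 0.2
  se <- sqrt(0.2 * 0.8 / 100000)
  expect_lt(abs(mean(et2$cause == "krt") - 0.2), 3 * se)
  # overall time is exponential with the summed rate
  expect_equal(mean(et2$time_years), 10, tolerance = 0.15)
  expect_error(simulate_event_times(NA, 0, cfg2), "finite")
})

test_that("piecewise-constant sampler matches its analytic CDF", {
  cfg <- sim_config(n_persons = 1,
                    krt_baseline_rates = c(0.05, 0, 0.2),
                    krt_baseline_breaks = c(1, 3),
                    death_baseline_rates = 1e-12,
                    death_baseline_breaks = numeric(0))
  set.seed(31)
  et <- simulate_event_times(rep(0, 50000), rep(-30, 50000), cfg)
  t <- et$time_years
  # no event can fall inside the zero-hazard segment (1,3)
  expect_identical(sum(t > 1 & t < 3), 0L)
  B <- function(x) 0.05 * pmin(x, 1) + 0.2 * pmax(x - 3, 0)
  for (x in c(0.5, 1, 3.5, 6)) {
    p <- 1 - exp(-B(x))
    expect_lt(abs(mean(t <= x) - p), 3 * sqrt(p * (1 - p) / 50000) + 1e-9)
  }
})

test_that("observed event fractions match numerical integration of the hazards", {
  # deterministic covariates so every person shares one linear predictor
  cfg <- recovery_config(20000, seed = 55, krt_rate = 0.02, death_rate = 0.06,
                         age_sd = 1e-9, egfr_sd = 1e-9, log_acr_sd = 1e-9,
                         emigration_rate = 0.01)
  tabs <- simulate_cohort(cfg)
  entry <- tabs$lab_tests$date[tabs$lab_tests$analyte == "creatinine"]
  entry <- entry[match(tabs$persons$person_id,
                       tabs$lab_tests$person_id[tabs$lab_tests$analyte ==
                                                  "creatinine"])]
  tau <- as.numeric(cfg$study_end - entry) / 365.25
  male <- tabs$persons$sex == "male"
  lp_of <- function(m) {
    zz <- c(cfg$age_mean / 10, as.numeric(m), cfg$egfr_mean / 5,
            cfg$log_acr_mean) - cfg$centering
    c(krt = sum(zz * cfg$krt_lp_coeffs), death = sum(zz * cfg$death_lp_coeffs))
  }
  p_krt <- function(m, tau_i) {
    lp <- lp_of(m)
    h1 <- 0.02 * exp(lp[["krt"]])
    h2 <- 0.06 * exp(lp[["death"]])
    mu <- cfg$emigration_rate
    tot <- h1 + h2 + mu
    h1 / tot * (1 - exp(-tot * tau_i))
  }
  expected <- mean(ifelse(male, p_krt(TRUE, tau), p_krt(FALSE, tau)))
  observed <- mean(!is.na(tabs$outcomes$krt_date))
  se <- sqrt(expected * (1 - expected) / nrow(tabs$persons))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("repeated test counts have the configured median and spread", {
  cfg <- sim_config(n_persons = 4000, seed = 9, emigration_rate = 0,
                    death_baseline_rates = 1e-9)
  tabs <- simulate_cohort(cfg)
  counts <- table(tabs$lab_tests$person_id[tabs$lab_tests$analyte ==
                                             "creatinine"])
  expect_equal(unname(median(counts)), 2)
  expect_lte(quantile(counts, 0.25), 2)
  expect_gte(quantile(counts, 0.75), 4)
})

test_that("cohort tables round-trip through CSV", {
  cfg <- sim_config(n_persons = 60, seed = 8)
  tabs <- simulate_cohort(cfg)
  d <- file.path(tempdir(), "cohort_csv")
  write_cohort_tables(tabs, d)
  back <- read_cohort_tables(d)
  expect_equal(back$persons$birth_date, tabs$persons$birth_date)
  expect_equal(back$lab_tests$value, tabs$lab_tests$value)
  expect_equal(back$outcomes$krt_date, tabs$outcomes$krt_date)
  # YAML config round trip
  y <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, y)
  cfg2 <- read_sim_config(y)
  expect_equal(cfg2$krt_baseline_rates, cfg$krt_baseline_rates)
  expect_identical(simulate_cohort(cfg2)$outcomes, tabs$outcomes)
})
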