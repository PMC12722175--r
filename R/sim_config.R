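AHT_CLASSES <- c("acei", "arb", "beta_blocker", "ccb", "thiazide",
                 "loop_diuretic", "mra")

#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated regional
#' healthcare-utilisation registry of adults with reduced kidney function:
#' repeated creatinine/albuminuria testing, pharmacy dispensations of
#' antihypertensive drugs, and cause-specific hazards for kidney replacement
#' therapy (KRT) and death, with administrative and emigration censoring.
#'
#' Covariates enter the KRT cause-specific hazard through the same four
#' transformed covariates as the KFRE (age/10, male, eGFR/5, ln ACR), centred
#' at the KFRE centering constants, so a Cox recalibration on simulated
#' records has a recoverable truth.
#'
#' Defaults emulate the marginals of a Swedish regional CKD testing
#' population: median age about 76, 49% male, entry eGFR below 60 with
#' median about 54, median ACR about 21 mg/g, a median of 2 test occasions
#' per person (IQR roughly 1-5), about 1-2% observed KRT and 35-45% death
#' over a 2006-2021 window, 46% dipstick and 9% PCR albuminuria tests.
#'
#' @param n_persons number of persons (>= 0)
#' @param study_start,study_end study window (ISO dates)
#' @param entry_end latest entry date (default 30 days before `study_end`)
#' @param age_mean,age_sd,age_min,age_max truncated-normal entry age (years)
#' @param male_frac proportion male
#' @param egfr_mean,egfr_sd,egfr_min,egfr_max truncated-normal entry eGFR,
#'   upper bound 60 by design (entry criterion)
#' @param log_acr_mean,log_acr_sd person-level ln ACR (mg/g)
#' @param tests_nb_mu,tests_nb_size occasions per person = 1 +
#'   `rnbinom(size, mu)`
#' @param krt_baseline_rates,krt_baseline_breaks piecewise-constant KRT
#'   baseline hazard (per year) with break points in years; the default
#'   rates reproduce the non-North American KFRE baseline survival at 2 and
#'   5 years at the centering point; the third piece beyond 5 years tempers
#'   the decline-driven late hazard growth so the observed KRT fraction
#'   stays near registry levels without touching the 2y/5y calibration
#' @param death_baseline_rates,death_baseline_breaks same for death
#' @param krt_lp_coeffs,death_lp_coeffs coefficients on the centred KFRE
#'   transforms for each cause-specific hazard
#' @param centering centering constants (transformed scale)
#' @param miscalibration_factor multiplier on the KRT baseline hazard, to
#'   emulate a population whose risk an imported model misestimates
#' @param dipstick_frac,pcr_frac albuminuria modality mix (rest native ACR)
#' @param mgmmol_frac fraction of native ACR/PCR values reported in mg/mmol
#' @param emigration_rate exponential emigration (censoring) rate per year
#' @param egfr_slope_mean,egfr_slope_sd latent linear eGFR decline
#'   (ml/min/1.73m2 per year)
#' @param egfr_noise_sd multiplicative (log-scale) eGFR measurement noise
#' @param acr_noise_sd within-person sd of observed ln ACR around the latent
#'   level
#' @param albuminuria_prob probability a test occasion includes an
#'   albuminuria test
#' @param albuminuria_offset_max max days between the creatinine and
#'   albuminuria test of one occasion
#' @param diabetes_frac,hypertension_frac comorbidity flag prevalences
#' @param aht_class_probs probabilities of 0..6 distinct antihypertensive
#'   classes per person
#' @param seed integer RNG seed (< 2^31)
#' @return validated `sim_config` list
#' @export
sim_config <- function(n_persons,
                       study_start = "2006-01-01",
                       study_end = "2021-12-31",
                       entry_end = NULL,
                       age_mean = 75.5, age_sd = 9.5,
                       age_min = 18, age_max = 100,
                       male_frac = 0.49,
                       egfr_mean = 56, egfr_sd = 9,
                       egfr_min = 5, egfr_max = 60,
                       log_acr_mean = 3.05, log_acr_sd = 0.9,
                       tests_nb_mu = 3.0, tests_nb_size = 0.4,
                       krt_baseline_rates = c(0.0061376, 0.0222565, 0.008),
                       krt_baseline_breaks = c(2, 5),
                       death_baseline_rates = 0.11,
                       death_baseline_breaks = numeric(0),
                       krt_lp_coeffs = c(-0.2201, 0.2467, -0.5567, 0.4510),
                       death_lp_coeffs = c(0.35, 0.20, -0.15, 0.10),
                       centering = c(7.036, 0.5642, 7.222, 5.137),
                       miscalibration_factor = 1,
                       dipstick_frac = 0.46, pcr_frac = 0.09,
                       mgmmol_frac = 0.2,
                       emigration_rate = 0.01,
                       egfr_slope_mean = -1.5, egfr_slope_sd = 1.0,
                       egfr_noise_sd = 0.08,
                       acr_noise_sd = 0.4,
                       albuminuria_prob = 0.9,
                       albuminuria_offset_max = 30,
                       diabetes_frac = 0.25,
                       hypertension_frac = 0.65,
                       aht_class_probs = c(0.23, 0.20, 0.22, 0.22,
                                           0.08, 0.04, 0.01),
                       seed = 1L) {
  cfg <- as.list(environment())
  # coerce vector fields (YAML readers may hand back lists)
  for (f in c("krt_baseline_rates", "krt_baseline_breaks",
              "death_baseline_rates", "death_baseline_breaks",
              "krt_lp_coeffs", "death_lp_coeffs", "centering",
              "aht_class_probs")) {
    cfg[[f]] <- as.numeric(unlist(cfg[[f]]))
  }
  cfg$study_start <- as_date(study_start)
  cfg$study_end <- as_date(study_end)
  cfg$entry_end <- if (is.null(entry_end)) cfg$study_end - 30 else
    as_date(entry_end)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  assert_field(is.numeric(cfg$n_persons) && length(cfg$n_persons) == 1 &&
                 cfg$n_persons >= 0 && cfg$n_persons == floor(cfg$n_persons),
               "n_persons", "must be a non-negative integer")
  assert_field(cfg$study_end > cfg$study_start, "study_end",
               "must be after study_start")
  assert_field(cfg$entry_end >= cfg$study_start &&
                 cfg$entry_end <= cfg$study_end, "entry_end",
               "must lie inside the study window")
  for (f in c("male_frac", "dipstick_frac", "pcr_frac", "mgmmol_frac",
              "albuminuria_prob", "diabetes_frac", "hypertension_frac")) {
    assert_field(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
                 f, "must be a proportion in [0,1]")
  }
  assert_field(cfg$dipstick_frac + cfg$pcr_frac <= 1, "dipstick_frac",
               "+ pcr_frac must not exceed 1")
  for (f in c("krt_baseline_rates", "death_baseline_rates")) {
    assert_field(is.numeric(cfg[[f]]) && length(cfg[[f]]) >= 1 &&
                   all(is.finite(cfg[[f]])) && all(cfg[[f]] >= 0),
                 f, "must be non-negative finite rates")
  }
  for (f in c("krt_lp_coeffs", "death_lp_coeffs", "centering")) {
    assert_field(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 4 &&
                   all(is.finite(cfg[[f]])), f, "must be 4 finite numbers")
  }
  assert_field(length(cfg$krt_baseline_rates) ==
                 length(cfg$krt_baseline_breaks) + 1,
               "krt_baseline_breaks",
               "must have one fewer element than krt_baseline_rates")
  assert_field(length(cfg$death_baseline_rates) ==
                 length(cfg$death_baseline_breaks) + 1,
               "death_baseline_breaks",
               "must have one fewer element than death_baseline_rates")
  assert_field(is.numeric(cfg$miscalibration_factor) &&
                 cfg$miscalibration_factor > 0, "miscalibration_factor",
               "must be positive")
  assert_field(is.numeric(cfg$emigration_rate) && cfg$emigration_rate >= 0,
               "emigration_rate", "must be non-negative")
  assert_field(length(cfg$aht_class_probs) == 7 &&
                 all(cfg$aht_class_probs >= 0) &&
                 abs(sum(cfg$aht_class_probs) - 1) < 1e-8,
               "aht_class_probs", "must be 7 probabilities summing to 1")
  assert_field(is.numeric(cfg$seed) && length(cfg$seed) == 1 &&
                 is.finite(cfg$seed) && abs(cfg$seed) < 2^31,
               "seed", "must be a 32-bit integer")
  invisible(cfg)
}

#' Read / write a sim_config as YAML
#'
#' @param path YAML file path
#' @param config a [sim_config()]
#' @return `read_sim_config()` returns a [sim_config()]
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sim_config, x)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$study_start <- format(x$study_start)
  x$study_end <- format(x$study_end)
  x$entry_end <- format(x$entry_end)
  yaml::write_yaml(x, path)
  invisible(path)
}
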