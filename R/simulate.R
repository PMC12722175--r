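# truncated normal via inverse-CDF (exact, vectorised)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# inverse-CDF sampling from a piecewise-constant baseline hazard scaled by
# exp(lp0 + g t): the per-person log-hazard drifts linearly in time (the
# latent eGFR decline feeding through its coefficient). Exact inversion of
# the cumulative hazard, vectorised over persons.
rpiecewise_exp_growth <- function(rates, breaks, lp0, g) {
  n <- length(lp0)
  target <- stats::rexp(n)
  w <- exp(lp0)
  k <- length(rates)
  lo <- c(0, breaks)
  hi <- c(breaks, Inf)
  t_out <- rep(NA_real_, n)
  cum <- numeric(n)
  small <- abs(g) < 1e-12
  for (j in seq_len(k)) {
    if (rates[j] == 0) next
    cap <- ifelse(small,
                  rates[j] * w * (hi[j] - lo[j]),
                  rates[j] * w * (exp(g * hi[j]) - exp(g * lo[j])) / g)
    # for g < 0 and hi = Inf: exp(g*Inf) = 0 -> finite cap
    need <- target - cum
    found <- which(is.na(t_out) & need < cap)
    if (length(found)) {
      nf <- need[found]
      wf <- w[found]
      gf <- g[found]
      t_out[found] <- ifelse(
        small[found],
        lo[j] + nf / (rates[j] * wf),
        log(exp(gf * lo[j]) + gf * nf / (rates[j] * wf)) / gf)
    }
    cum <- cum + ifelse(is.finite(cap), cap, 0)
  }
  t_out[is.na(t_out)] <- Inf
  t_out
}

# inverse-CDF sampling from a piecewise-constant hazard:
# cumulative hazard H(t) = relhaz * B(t), B piecewise linear with slopes
# `rates` between `breaks` (years); returns +Inf when the target exceeds
# the total achievable hazard (e.g. all rates zero).
rpiecewise_exp <- function(n, rates, breaks, relhaz = 1) {
  relhaz <- rep_len(relhaz, n)
  target <- stats::rexp(n) / relhaz
  k <- length(rates)
  lo <- c(0, breaks)
  dur <- c(diff(lo), Inf)
  cumb <- c(0, cumsum(rates[-k] * dur[-k]))   # B at segment starts
  out <- rep(Inf, n)
  for (j in seq_len(k)) {
    top <- if (j < k) cumb[j + 1] else Inf
    sel <- is.infinite(out) & target >= cumb[j] &
      (target < top | (j == k & rates[k] > 0))
    if (any(sel)) {
      if (rates[j] > 0) {
        out[sel] <- lo[j] + (target[sel] - cumb[j]) / rates[j]
      }
      # rate 0 segment: no event can fall inside; leave Inf unless a later
      # segment catches it (target >= next cumb), handled by the loop
      if (rates[j] == 0) out[sel] <- Inf
    }
  }
  out
}

#' Draw competing event times from cause-specific hazards
#'
#' Latent times are drawn independently for each cause from its
#' piecewise-constant baseline hazard scaled by `exp(lp)` (the KRT baseline
#' additionally by the configured miscalibration factor); the earlier cause
#' wins. No censoring is applied here. With a single baseline piece this is
#' the constant-hazard (competing exponentials) mode, for which
#' `P(cause = krt) = h1/(h1+h2)` in closed form.
#'
#' @param lp_krt,lp_death finite linear predictors (vectors, recycled)
#' @param config a [sim_config()] supplying the baseline hazards
#' @return data frame with `cause` (`"krt"`, `"death"`, or `"none"` when both
#'   hazards are zero) and `time_years`
#' @export
simulate_event_times <- function(lp_krt, lp_death, config) {
  n <- max(length(lp_krt), length(lp_death))
  lp_krt <- rep_len(as.numeric(lp_krt), n)
  lp_death <- rep_len(as.numeric(lp_death), n)
  if (any(!is.finite(lp_krt)) || any(!is.finite(lp_death))) {
    stop_input("simulate_event_times: linear predictors must be finite")
  }
  t_krt <- rpiecewise_exp(n, config$krt_baseline_rates *
                            config$miscalibration_factor,
                          config$krt_baseline_breaks, exp(lp_krt))
  t_death <- rpiecewise_exp(n, config$death_baseline_rates,
                            config$death_baseline_breaks, exp(lp_death))
  cause <- ifelse(t_krt == Inf & t_death == Inf, "none",
                  ifelse(t_krt <= t_death, "krt", "death"))
  data.frame(cause = cause, time_years = pmin(t_krt, t_death))
}

empty_cohort_tables <- function(config = NULL) {
  list(
    persons = data.frame(person_id = integer(), sex = character(),
                         birth_date = as.Date(character()),
                         diabetes = logical(), hypertension = logical()),
    lab_tests = data.frame(person_id = integer(),
                           date = as.Date(character()),
                           analyte = character(), value = numeric(),
                           unit = character(), category = character()),
    dispensations = data.frame(person_id = integer(),
                               date = as.Date(character()),
                               drug_class = character()),
    outcomes = data.frame(person_id = integer(),
                          krt_date = as.Date(character()),
                          death_date = as.Date(character()),
                          emigration_date = as.Date(character())),
    config = config)
}

#' Simulate a synthetic testing cohort
#'
#' Generates four person-level tables (persons, lab_tests, dispensations,
#' outcomes) with the statistical structure described in [sim_config()].
#' Each person enters at their first creatinine test; latent eGFR declines
#' linearly with per-test measurement noise; albuminuria is observed as
#' native ACR, PCR or dipstick; KRT and death times come from cause-specific
#' hazards driven by the entry covariates through the KFRE transforms;
#' emigration and the end of the study window censor observation.
#' Identical config and seed give identical output; the caller's RNG state
#' is left untouched.
#'
#' @param config a [sim_config()]
#' @return list of data frames `persons`, `lab_tests`, `dispensations`,
#'   `outcomes`, plus the `config`
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_persons == 0) return(empty_cohort_tables(config))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- as.integer(cfg$n_persons)
  id <- seq_len(n)
  male <- stats::runif(n) < cfg$male_frac
  age0 <- rtruncnorm(n, cfg$age_mean, cfg$age_sd, cfg$age_min, cfg$age_max)
  egfr0 <- rtruncnorm(n, cfg$egfr_mean, cfg$egfr_sd, cfg$egfr_min,
                      cfg$egfr_max)
  lnacr <- stats::rnorm(n, cfg$log_acr_mean, cfg$log_acr_sd)
  slope <- stats::rnorm(n, cfg$egfr_slope_mean, cfg$egfr_slope_sd)
  diabetes <- stats::runif(n) < cfg$diabetes_frac
  hypertension <- stats::runif(n) < cfg$hypertension_frac
  n_aht <- sample(0:6, n, replace = TRUE, prob = cfg$aht_class_probs)

  span_entry <- as.integer(cfg$entry_end - cfg$study_start)
  entry <- cfg$study_start + floor(stats::runif(n) * (span_entry + 1))

  # cause-specific event times from entry covariates (KFRE transforms)
  z <- cbind(age0 / 10, as.numeric(male), egfr0 / 5, lnacr)
  zc <- sweep(z, 2, cfg$centering, "-")
  lp_krt <- drop(zc %*% cfg$krt_lp_coeffs)
  lp_death <- drop(zc %*% cfg$death_lp_coeffs)
  # the latent eGFR decline drifts each cause-specific log hazard in time
  g_krt <- cfg$krt_lp_coeffs[3] * slope / 5
  g_death <- cfg$death_lp_coeffs[3] * slope / 5
  t_krt <- rpiecewise_exp_growth(cfg$krt_baseline_rates *
                                   cfg$miscalibration_factor,
                                 cfg$krt_baseline_breaks, lp_krt, g_krt)
  t_death <- rpiecewise_exp_growth(cfg$death_baseline_rates,
                                   cfg$death_baseline_breaks, lp_death,
                                   g_death)
  t_emig <- if (cfg$emigration_rate > 0) {
    stats::rexp(n, cfg$emigration_rate)
  } else rep(Inf, n)

  t_event <- pmin(t_krt, t_death)
  first <- ifelse(t_emig < t_event, "emig",
                  ifelse(t_event == Inf, "none",
                         ifelse(t_krt <= t_death, "krt", "death")))
  event_date <- entry + round(pmin(t_event, t_emig) * DAYS_PER_YEAR)
  observed <- first != "none" & event_date <= cfg$study_end
  krt_date <- as.Date(ifelse(observed & first == "krt", event_date, NA),
                      origin = "1970-01-01")
  death_date <- as.Date(ifelse(observed & first == "death", event_date, NA),
                        origin = "1970-01-01")
  emig_date <- as.Date(ifelse(observed & first == "emig", event_date, NA),
                       origin = "1970-01-01")
  obs_end <- pmin(cfg$study_end,
                  as.Date(ifelse(observed, event_date, Inf),
                          origin = "1970-01-01"))

  persons <- data.frame(person_id = id,
                        sex = ifelse(male, "male", "female"),
                        birth_date = entry - round(age0 * DAYS_PER_YEAR),
                        diabetes = diabetes, hypertension = hypertension)
  outcomes <- data.frame(person_id = id, krt_date = krt_date,
                         death_date = death_date,
                         emigration_date = emig_date)

  # test occasions: first at entry, the rest uniform over the observed span
  n_occ <- 1L + stats::rnbinom(n, size = cfg$tests_nb_size,
                               mu = cfg$tests_nb_mu)
  span <- pmax(as.integer(obs_end - entry), 0L)
  n_occ[span == 0L] <- 1L
  pidx <- rep.int(id, n_occ)
  off <- floor(stats::runif(length(pidx)) * (span[pidx] + 1L))
  first_occ <- c(TRUE, pidx[-1] != pidx[-length(pidx)])
  off[first_occ] <- 0L
  occ_date <- entry[pidx] + off
  yrs <- off / DAYS_PER_YEAR

  age_at <- age0[pidx] + yrs
  egfr_true <- pmax(egfr0[pidx] + slope[pidx] * yrs, 2)
  egfr_obs <- egfr_true * exp(stats::rnorm(length(pidx), 0, cfg$egfr_noise_sd))
  cr_val <- creatinine_from_egfr(egfr_obs, age_at, male[pidx])
  creat <- data.frame(person_id = pidx, date = occ_date,
                      analyte = "creatinine", value = round(cr_val, 1),
                      unit = "umol/L", category = NA_character_)

  has_alb <- stats::runif(length(pidx)) < cfg$albuminuria_prob
  ai <- which(has_alb)
  alb_off <- round(stats::runif(length(ai), -cfg$albuminuria_offset_max,
                                cfg$albuminuria_offset_max))
  alb_date <- pmin(pmax(occ_date[ai] + alb_off, cfg$study_start),
                   obs_end[pidx[ai]])
  acr_obs <- exp(lnacr[pidx[ai]] +
                   stats::rnorm(length(ai), 0, cfg$acr_noise_sd))
  u <- stats::runif(length(ai))
  modality <- ifelse(u < cfg$dipstick_frac, "dipstick",
                     ifelse(u < cfg$dipstick_frac + cfg$pcr_frac, "pcr",
                            "acr"))
  # PCR values consistent with the shipped fallback factor (ACR = 0.65*PCR)
  raw <- ifelse(modality == "pcr", acr_obs / 0.65, acr_obs)
  in_mgmmol <- modality != "dipstick" &
    stats::runif(length(ai)) < cfg$mgmmol_frac
  value <- ifelse(modality == "dipstick", NA_real_,
                  round(ifelse(in_mgmmol, raw / MGMMOL_TO_MGG, raw), 2))
  unit <- ifelse(modality == "dipstick", NA_character_,
                 ifelse(in_mgmmol, "mg/mmol", "mg/g"))
  category <- ifelse(modality != "dipstick", NA_character_,
                     as.character(cut(acr_obs, c(-Inf, 30, 150, 300, 1000, Inf),
                                      labels = DIPSTICK_LEVELS)))
  alb <- data.frame(person_id = pidx[ai], date = alb_date, analyte = modality,
                    value = value, unit = unit, category = category)
  lab_tests <- rbind(creat, alb)
  lab_tests <- lab_tests[order(lab_tests$person_id, lab_tests$date,
                               lab_tests$analyte), ]
  rownames(lab_tests) <- NULL

  # antihypertensive fills shortly before each test occasion; distinct
  # classes per person are a rotation of the class list
  start <- sample.int(7L, n, replace = TRUE)
  kk <- n_aht[pidx]
  di <- which(kk > 0)
  if (length(di)) {
    rep_occ <- rep.int(di, kk[di])
    class_pos <- sequence(kk[di]) - 1L
    cls <- AHT_CLASSES[((start[pidx[rep_occ]] + class_pos) %% 7L) + 1L]
    fill_date <- occ_date[rep_occ] -
      floor(stats::runif(length(rep_occ)) * 150)
    dispensations <- data.frame(person_id = pidx[rep_occ],
                                date = fill_date, drug_class = cls)
    dispensations <- dispensations[order(dispensations$person_id,
                                         dispensations$date,
                                         dispensations$drug_class), ]
    rownames(dispensations) <- NULL
  } else {
    dispensations <- empty_cohort_tables()$dispensations
  }

  list(persons = persons, lab_tests = lab_tests,
       dispensations = dispensations, outcomes = outcomes, config = cfg)
}

#' Write / read the four cohort tables as CSV
#'
#' Tables are written as `persons.csv`, `lab_tests.csv`, `dispensations.csv`
#' and `outcomes.csv` with ISO-8601 dates, creatinine in umol/L, ACR/PCR in
#' mg/g or mg/mmol (unit column), dipstick as `neg/trace/1+/2+/3+` in the
#' `category` column.
#'
#' @param tables list as returned by [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return `read_cohort_tables()` returns the list of tables
#' @export
write_cohort_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("persons", "lab_tests", "dispensations", "outcomes")) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort_tables
#' @export
read_cohort_tables <- function(dir) {
  rd <- function(nm, datecols) {
    x <- utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                         stringsAsFactors = FALSE)
    for (dc in datecols) x[[dc]] <- as.Date(x[[dc]])
    x
  }
  list(persons = rd("persons", "birth_date"),
       lab_tests = rd("lab_tests", "date"),
       dispensations = rd("dispensations", "date"),
       outcomes = rd("outcomes", c("krt_date", "death_date",
                                   "emigration_date")))
}
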