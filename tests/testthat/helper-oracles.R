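# Independent brute-force oracles used across the suite. These are written
# naively (per-time filtering, no incremental bookkeeping) on purpose so
# they constitute a second route to the same estimands.

# product-limit CIF/survival computed subject-by-subject
bf_aj <- function(time, event) {
  ts <- sort(unique(time))
  S <- 1
  cif_krt <- 0
  cif_death <- 0
  out <- data.frame(time = ts, surv = NA_real_, cif_krt = NA_real_,
                    cif_death = NA_real_)
  for (i in seq_along(ts)) {
    t <- ts[i]
    n_at_risk <- sum(time >= t)
    d_krt <- sum(time == t & event == "krt")
    d_death <- sum(time == t & event == "death")
    cif_krt <- cif_krt + S * d_krt / n_at_risk
    cif_death <- cif_death + S * d_death / n_at_risk
    S <- S * (1 - (d_krt + d_death) / n_at_risk)
    out$surv[i] <- S
    out$cif_krt[i] <- cif_krt
    out$cif_death[i] <- cif_death
  }
  out
}

# empirical binary ROC point at an inclusive threshold
bf_binary_point <- function(scores, labels, c) {
  c(sens = mean(scores[labels] >= c),
    spec = mean(scores[!labels] < c))
}

# classical two-category binary NRI
bf_binary_nri <- function(events, old, new) {
  up <- !old & new
  down <- old & !new
  nri_e <- (sum(up & events) - sum(down & events)) / sum(events)
  nri_ne <- (sum(down & !events) - sum(up & !events)) / sum(!events)
  c(events = nri_e, nonevents = nri_ne, overall = nri_e + nri_ne)
}

# Efron-tie Cox log partial likelihood, evaluated directly
efron_loglik <- function(beta, z, time, status) {
  lp <- drop(z %*% beta)
  w <- exp(lp)
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(w[R])
    sD <- sum(w[D])
    ll <- ll + sum(lp[D]) -
      sum(log(sR - (seq_len(d) - 1) / d * sD))
  }
  ll
}

# records data frame from parallel vectors
rec_df <- function(time, event) {
  data.frame(followup_days = time, event = event)
}

# random competing-risk records (uncensored option), seeded by caller
random_records <- function(n, censor = TRUE) {
  time <- ceiling(rexp(n, 1 / 400))
  ev <- sample(c("krt", "death", if (censor) "censored"), n, replace = TRUE)
  rec_df(time, ev)
}

# a clean simulation config where the Cox truth holds exactly per record
recovery_config <- function(n, seed, krt_rate = 2.5,
                            krt_breaks = numeric(length(krt_rate) - 1),
                            death_rate = 1e-9,
                            emigration_rate = 0, entry_end = NULL, ...) {
  if (length(krt_breaks) == 0) krt_breaks <- numeric(0)
  sim_config(n_persons = n, seed = seed,
             tests_nb_mu = 0, tests_nb_size = 1,
             krt_baseline_rates = krt_rate, krt_baseline_breaks = krt_breaks,
             death_baseline_rates = death_rate,
             death_baseline_breaks = numeric(0),
             emigration_rate = emigration_rate,
             egfr_slope_mean = 0, egfr_slope_sd = 0, egfr_noise_sd = 0,
             acr_noise_sd = 0, albuminuria_prob = 1,
             albuminuria_offset_max = 0, dipstick_frac = 0, pcr_frac = 0,
             mgmmol_frac = 0, entry_end = entry_end, ...)
}

# simulate -> observation records with follow-up attached
sim_records <- function(cfg, horizon_years = 200) {
  tabs <- simulate_cohort(cfg)
  obs <- build_observations(tabs)
  ex <- apply_cohort_exclusions(obs, tabs$outcomes)
  rec <- attach_followup(ex$records, tabs$outcomes, cfg$study_end,
                         horizon_years)
  rec[rec$followup_days > 0, , drop = FALSE]
}
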