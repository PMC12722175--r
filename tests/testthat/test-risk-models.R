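centering_record <- function() {
  data.frame(age_years = 70.36, is_male = 0.5642, egfr = 36.11,
             acr_mgg = exp(5.137))
}

test_that("KFRE linear predictor is zero at the centering point", {
  expect_equal(kfre_linear_predictor(centering_record()), 0,
               tolerance = 1e-12)
})

test_that("KFRE linear predictor and risk match direct evaluation", {
  rec <- data.frame(age_years = 65, is_male = TRUE, egfr = 25, acr_mgg = 300)
  lp <- kfre_linear_predictor(rec)
  lp_direct <- -0.2201 * (6.5 - 7.036) + 0.2467 * (1 - 0.5642) -
    0.5567 * (5 - 7.222) + 0.4510 * (log(300) - 5.137)
  expect_equal(lp, lp_direct, tolerance = 1e-12)
  expect_equal(lp, 1.718, tolerance = 1e-3)
  expect_equal(kfre_risk(lp, kfre_published(), 5), 1 - 0.9240^exp(lp),
               tolerance = 1e-12)
  expect_equal(kfre_risk(lp, kfre_published(), 5), 0.356, tolerance = 1e-3)
})

test_that("risk at lp = 0 equals 1 - S0 and limits behave", {
  m <- kfre_published()
  expect_equal(kfre_risk(0, m, 5), 1 - 0.9240, tolerance = 1e-12)
  expect_equal(kfre_risk(0, m, 2), 1 - 0.9878, tolerance = 1e-12)
  mo <- kfre_published("original")
  expect_equal(kfre_risk(0, mo, 5), 1 - 0.8996, tolerance = 1e-12)
  expect_equal(kfre_risk(-50, m, 5), 0, tolerance = 1e-12)
  expect_lt(kfre_risk(20, m, 5), 1 + 1e-12)
  expect_error(kfre_risk(0, m, 7), "horizon")
})

test_that("risk is monotone in each covariate with the published signs", {
  base <- data.frame(age_years = 70, is_male = FALSE, egfr = 40,
                     acr_mgg = 50)
  risk_of <- function(rec) score_cohort(rec, kfre_published(), 5)
  grid <- function(col, vals) {
    rec <- base[rep(1, length(vals)), ]
    rec[[col]] <- vals
    risk_of(rec)
  }
  expect_true(all(diff(grid("age_years", seq(20, 90, 5))) < 0))
  expect_true(all(diff(grid("egfr", seq(10, 59, 2))) < 0))
  expect_true(all(diff(grid("acr_mgg", exp(seq(0, 8, 0.5)))) > 0))
  expect_gt(risk_of(transform(base, is_male = TRUE)), risk_of(base))
})

test_that("scoring is pure, aligned, and rejects bad inputs", {
  rec <- data.frame(age_years = c(70, 70), is_male = c(TRUE, TRUE),
                    egfr = c(30, 30), acr_mgg = c(90, 90))
  r <- score_cohort(rec)
  expect_length(r, 2)
  expect_identical(r[1], r[2])
  expect_length(score_cohort(rec[1, ]), 1)
  expect_error(score_cohort(transform(rec, acr_mgg = c(-1, 5))), "ACR")
  expect_error(score_cohort(transform(rec, egfr = c(0, 5))), "eGFR")
})

test_that("model JSON round-trips", {
  m <- kfre_published("original")
  p <- tempfile(fileext = ".json")
  write_kfre_model(m, p)
  m2 <- read_kfre_model(p)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$baseline_survival, m$baseline_survival)
  expect_identical(m2$name, m$name)
})

test_that("Efron tie handling matches a brute-force partial likelihood", {
  # 12 records, heavy ties in event times
  rec <- data.frame(
    age_years = c(60, 72, 81, 55, 66, 70, 75, 62, 68, 77, 59, 73),
    is_male = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE,
                TRUE, FALSE, TRUE, FALSE),
    egfr = c(20, 35, 28, 45, 50, 18, 33, 41, 25, 38, 55, 30),
    acr_mgg = c(500, 30, 120, 60, 15, 900, 200, 45, 350, 80, 25, 150),
    followup_days = c(100, 100, 100, 250, 250, 400, 400, 400, 600, 800,
                      900, 1000),
    event = c("krt", "krt", "censored", "krt", "censored", "krt", "krt",
              "censored", "krt", "censored", "krt", "censored"))
  fit <- fit_recalibration(rec, horizon_years = c(2, 5), min_events = 1)
  z <- cbind(rec$age_years / 10, as.numeric(rec$is_male), rec$egfr / 5,
             log(rec$acr_mgg))
  z <- sweep(z, 2, kfre_published()$centering, "-")
  ll_bf <- efron_loglik(fit$coefficients$estimate, z, rec$followup_days,
                        as.numeric(rec$event == "krt"))
  expect_equal(ll_bf, fit$loglik[2], tolerance = 1e-8)
  # the fitted beta maximises the brute-force likelihood
  opt <- optim(rep(0, 4), function(b) -efron_loglik(b, z, rec$followup_days,
                                                    as.numeric(rec$event == "krt")),
               method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(opt$par, fit$coefficients$estimate, tolerance = 1e-4)
})

test_that("cluster-robust standard errors are available and positive", {
  cfg <- recovery_config(1200, seed = 15, krt_rate = 0.5)
  rec <- sim_records(cfg)
  fit <- fit_recalibration(rec, c(2, 5), cluster_se = TRUE)
  expect_true(all(fit$coefficients$se > 0))
  expect_length(fit$coefficients$estimate, 4)
})

test_that("null covariates recover zero and S0 is monotone", {
  cfg <- recovery_config(3000, seed = 12)
  rec <- sim_records(cfg)
  set.seed(13)
  # permute outcomes against covariates -> null association
  perm <- sample.int(nrow(rec))
  rec$followup_days <- rec$followup_days[perm]
  rec$event <- rec$event[perm]
  fit <- fit_recalibration(rec, c(2, 5))
  z <- abs(fit$coefficients$estimate) / fit$coefficients$se
  expect_true(all(z < 3))
  expect_gte(fit$baseline_survival[["2"]], fit$baseline_survival[["5"]])
  expect_error(fit_recalibration(rec[rec$event != "krt", ], c(2, 5)),
               "events")
})
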