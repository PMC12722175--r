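mk_tests <- function(pid, days, origin = as.Date("2010-01-01")) {
  data.frame(person_id = pid, date = origin + days)
}

test_that("pairing follows the nearest-in-window, latest-index convention", {
  # same-day pair indexes on that day
  p <- pair_tests(mk_tests(1, 50), mk_tests(1, 50))
  expect_identical(nrow(p), 1L)
  expect_identical(p$index_date, as.Date("2010-01-01") + 50)
  # 200 days apart: pair, index at the later date
  p2 <- pair_tests(mk_tests(1, 0), mk_tests(1, 200))
  expect_identical(p2$index_date, as.Date("2010-01-01") + 200)
  # 400 days apart: outside the window
  expect_identical(nrow(pair_tests(mk_tests(1, 0), mk_tests(1, 400))), 0L)
  # boundary: exactly window_days apart still pairs
  expect_identical(nrow(pair_tests(mk_tests(1, 0), mk_tests(1, 365))), 1L)
  # equidistant candidates: the earlier albuminuria test wins
  p3 <- pair_tests(mk_tests(1, 100), mk_tests(1, c(70, 130)))
  expect_identical(p3$alb_row, 1L)
  expect_identical(p3$index_date, as.Date("2010-01-01") + 100)
  # persons do not cross-pair
  p4 <- pair_tests(mk_tests(1, 0), mk_tests(2, 0))
  expect_identical(nrow(p4), 0L)
  # empty inputs give empty output
  expect_identical(nrow(pair_tests(mk_tests(1, 0)[0, ], mk_tests(1, 0))), 0L)
})

test_that("all-pairs mode cross-joins within the window", {
  p <- pair_tests(mk_tests(1, c(0, 10)), mk_tests(1, c(5, 300, 800)),
                  all_pairs = TRUE)
  # creat day 0: alb 5, 300; creat day 10: alb 5, 300 -> 4 pairs
  expect_identical(nrow(p), 4L)
  expect_true(all(p$index_date >= as.Date("2010-01-01")))
})

test_that("cohort exclusions act on the first record only", {
  rec <- data.frame(
    person_id = c(1, 1, 2, 2, 3, 4),
    index_date = as.Date("2010-01-01") + c(0, 100, 0, 100, 0, 0),
    egfr = c(62, 55, 55, 61, 50, 45))
  out <- data.frame(person_id = 1:4,
                    krt_date = as.Date(c(NA, NA, NA, "2009-06-01")),
                    death_date = as.Date(c(NA, NA, NA, NA)),
                    emigration_date = as.Date(rep(NA, 4)))
  ex <- apply_cohort_exclusions(rec, out)
  # person 1: first record eGFR 62 -> dropped entirely
  expect_false(1 %in% ex$records$person_id)
  # person 2: first eGFR 55 -> retained with BOTH records (even the 61)
  expect_identical(sum(ex$records$person_id == 2), 2L)
  # person 4: prevalent KRT -> dropped
  expect_false(4 %in% ex$records$person_id)
  expect_identical(unname(ex$exclusions["egfr_ge60"]), 1L)
  expect_identical(unname(ex$exclusions["prevalent_krt"]), 1L)
  expect_identical(unname(ex$exclusions["persons_excluded"]), 2L)
  # stricter per-record filter on demand
  ex2 <- apply_cohort_exclusions(rec, out, drop_later_ge60 = TRUE)
  expect_identical(sum(ex2$records$person_id == 2), 1L)
  # filters are idempotent
  ex3 <- apply_cohort_exclusions(ex$records, out)
  expect_identical(ex3$records, ex$records)
})

test_that("follow-up and event assignment match date arithmetic", {
  rec <- data.frame(person_id = 1:3,
                    index_date = as.Date(c("2010-01-01", "2018-06-01",
                                           "2010-01-01")),
                    egfr = 50)
  out <- data.frame(person_id = 1:3,
                    krt_date = as.Date(c("2012-01-01", NA, "2016-06-01")),
                    death_date = as.Date(c(NA, NA, NA)),
                    emigration_date = as.Date(c(NA, NA, NA)))
  r <- attach_followup(rec, out, admin_end = "2021-12-31", horizon_years = 5)
  expect_identical(r$event, c("krt", "censored", "censored"))
  expect_identical(r$followup_days, c(730, 1309, 1826))
  # death before index is a data inconsistency
  out$death_date[2] <- as.Date("2018-01-01")
  expect_error(attach_followup(rec, out, "2021-12-31", 5), "before index")
  # follow-up never exceeds the horizon
  expect_true(all(r$followup_days <= horizon_days(5)))
})

test_that("antihypertensive counting is distinct-class over a half-open window", {
  idx <- as.Date("2010-06-01")
  disp <- data.frame(
    person_id = c(1, 1, 1, 1, 1, 1, 1, 2),
    date = c(idx - c(10, 20, 30, 40), idx - 10, idx - 184, idx, idx - 5),
    drug_class = c("acei", "arb", "ccb", "thiazide", "acei", "mra",
                   "loop_diuretic", "acei"))
  n <- count_antihypertensives(disp, c(1, 2), c(idx, idx))
  # person 1: acei,arb,ccb,thiazide + same-day loop = 5 distinct;
  # the repeat acei fill does not add; mra at exactly 184 days is outside
  expect_identical(n, c(5L, 1L))
  # same class five times counts once
  d2 <- data.frame(person_id = 1, date = idx - (1:5) * 10,
                   drug_class = "acei")
  expect_identical(count_antihypertensives(d2, 1, idx), 1L)
  # boundary: 184 days before with lookback 183 is excluded (the window is
  # half-open, so even lookback 184 leaves the boundary fill out)
  d3 <- data.frame(person_id = 1, date = idx - 184, drug_class = "arb")
  expect_identical(count_antihypertensives(d3, 1, idx), 0L)
  expect_identical(count_antihypertensives(d3, 1, idx, lookback_days = 185),
                   1L)
})

test_that("sensitivity subsets behave and are deterministic", {
  fx <- make_toy_fixture()
  obs <- build_observations(fx)
  ex <- apply_cohort_exclusions(obs, fx$outcomes)
  rec <- attach_followup(ex$records, fx$outcomes, fx$admin_end, 5)
  one <- subset_for_sensitivity(rec, "one_random_per_person", seed = 3)
  expect_identical(nrow(one), length(unique(rec$person_id)))
  expect_identical(anyDuplicated(one$person_id), 0L)
  expect_identical(one, subset_for_sensitivity(rec, "one_random_per_person",
                                               seed = 3))
  acr <- subset_for_sensitivity(rec, "acr_only")
  expect_true(all(acr$albuminuria_source %in% c("acr", "pcr")))
  expect_identical(nrow(acr), nrow(rec) - 1L)  # one dipstick record (person 9)
  expect_error(subset_for_sensitivity(rec, "period"), "period")
  per <- subset_for_sensitivity(rec, "period",
                                period = rec$calendar_period[1])
  expect_true(all(per$calendar_period == rec$calendar_period[1]))
  # filters are idempotent and non-increasing
  expect_identical(subset_for_sensitivity(acr, "acr_only"), acr)
  expect_lte(nrow(acr), nrow(rec))
})

test_that("toy fixture enumerations hold end to end", {
  fx <- make_toy_fixture()
  obs <- build_observations(fx)
  # person 6 (tests 400 days apart) contributes no record
  expect_false(6 %in% obs$person_id)
  # person 7 is refractory-hypertension positive with exactly 4 classes
  expect_identical(obs$n_antihypertensives_6mo[obs$person_id == 7], 4L)
  # person 9's index is the (later) dipstick date
  expect_identical(obs$index_date[obs$person_id == 9],
                   as.Date("2010-03-11"))
  ex <- apply_cohort_exclusions(obs, fx$outcomes)
  expect_identical(unname(ex$exclusions["egfr_ge60"]), 1L)   # person 8
  expect_identical(unname(ex$exclusions["persons_excluded"]), 1L)
  expect_identical(nrow(ex$records), 8L)
  rec <- attach_followup(ex$records, fx$outcomes, fx$admin_end, 5)
  five <- rec[rec$person_id %in% 1:5, ]
  expect_identical(five$followup_days, as.numeric(1:5))
  expect_identical(five$event,
                   c("krt", "death", "censored", "krt", "censored"))
})
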