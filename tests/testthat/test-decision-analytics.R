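toy10 <- function() {
  # 10 uncensored records: 4 referred (2 KRT), 6 not referred (1 KRT)
  rec <- rec_df(c(100, 200, 3000, 3000, 400, 3000, 3000, 3000, 3000, 3000),
                c("krt", "krt", "censored", "censored", "krt", "censored",
                  "censored", "censored", "censored", "censored"))
  list(rec = rec, referred = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6)))
}

test_that("classification counts match the hand count", {
  t10 <- toy10()
  cl <- classification_table(t10$rec, t10$referred, 5)
  expect_identical(cl$n_eligible, 4L)
  expect_identical(cl$tp, 2L)
  expect_identical(cl$fp, 2L)
  expect_equal(cl$ppv, 0.5, tolerance = 1e-12)
  expect_identical(cl$n_noneligible, 6L)
  expect_identical(cl$fn, 1L)
  expect_identical(cl$tn, 5L)
  expect_equal(cl$npv, 5 / 6, tolerance = 1e-12)
})

test_that("degenerate rules carry conventions and flags", {
  t10 <- toy10()
  all_in <- classification_table(t10$rec, rep(TRUE, 10), 5)
  expect_identical(all_in$fn, 0L)
  expect_true(all_in$npv_degenerate)
  expect_identical(all_in$npv, 1)
  none <- classification_table(t10$rec, rep(FALSE, 10), 5)
  expect_true(none$ppv_degenerate)
})

test_that("cif-weighted cells equal raw counts on uncensored data", {
  t10 <- toy10()
  raw <- classification_table(t10$rec, t10$referred, 5, "raw_counts")
  cw <- classification_table(t10$rec, t10$referred, 5, "cif_weighted")
  expect_equal(cw$tp, raw$tp, tolerance = 1e-12)
  expect_equal(cw$fn, raw$fn, tolerance = 1e-12)
  expect_equal(cw$npv, raw$npv, tolerance = 1e-12)
})

test_that("reclassification matrices partition the cohort", {
  t10 <- toy10()
  old <- t10$referred
  new <- c(TRUE, TRUE, FALSE, FALSE, TRUE, rep(FALSE, 5))
  m <- reclassification_matrix(t10$rec, old, new)
  expect_identical(m["old_yes", "new_no"], 2L)
  expect_identical(m["old_no", "new_yes"], 1L)
  expect_identical(m["old_yes", "new_yes"], 2L)
  expect_identical(m["old_no", "new_no"], 5L)
  expect_identical(sum(m), 10L)
  expect_equal(sum(attr(m, "pct")), 100, tolerance = 1e-12)
  # a rule against itself has empty off-diagonals
  m2 <- reclassification_matrix(t10$rec, old, old)
  expect_identical(m2["old_yes", "new_no"] + m2["old_no", "new_yes"], 0L)
})

test_that("NRI reduces to the classical binary NRI and is antisymmetric", {
  # N = 10, 3 events; new rule de-refers 2 non-events, loses no events
  rec <- rec_df(c(100, 150, 200, rep(3000, 7)),
                c(rep("krt", 3), rep("censored", 7)))
  events <- rec$event == "krt"
  old <- c(rep(TRUE, 7), rep(FALSE, 3))
  new <- old
  new[c(6, 7)] <- FALSE
  res <- nri(rec, old, new, 5)
  expect_equal(res$nri_events, 0, tolerance = 1e-12)
  expect_equal(res$nri_nonevents, 2 / 7, tolerance = 1e-12)
  expect_equal(res$nri_overall, res$nri_events + res$nri_nonevents,
               tolerance = 1e-12)
  bf <- bf_binary_nri(events, old, new)
  expect_equal(res$nri_events, bf[["events"]], tolerance = 1e-12)
  expect_equal(res$nri_nonevents, bf[["nonevents"]], tolerance = 1e-12)
  # antisymmetry under swapping the rules
  swapped <- nri(rec, new, old, 5)
  expect_equal(swapped$nri_events, -res$nri_events, tolerance = 1e-12)
  expect_equal(swapped$nri_nonevents, -res$nri_nonevents, tolerance = 1e-12)
  expect_equal(swapped$nri_overall, -res$nri_overall, tolerance = 1e-12)
  # rule against itself is exactly zero
  same <- nri(rec, old, old, 5)
  expect_identical(same$nri_overall, 0)
})

test_that("binary NRI reduction holds on random uncensored configurations", {
  set.seed(101)
  for (i in 1:10) {
    n <- 60
    events <- runif(n) < 0.4
    rec <- rec_df(ifelse(events, sample(50:1500, n, TRUE), 3000),
                  ifelse(events, "krt", "censored"))
    old <- runif(n) < 0.5
    new <- runif(n) < 0.5
    res <- nri(rec, old, new, 5)
    bf <- bf_binary_nri(events, old, new)
    expect_equal(res$nri_events, bf[["events"]], tolerance = 1e-12)
    expect_equal(res$nri_nonevents, bf[["nonevents"]], tolerance = 1e-12)
  }
})

test_that("decision curve identities hold", {
  # overall F(t) = 0.2, uncensored
  rec <- rec_df(c(100, 300, rep(3000, 8)),
                c("krt", "krt", rep("censored", 8)))
  dca <- decision_curve(rec, fixed_rules = list(),
                        pt_grid = c(0.05, 0.1, 0.25))
  tn <- dca[dca$strategy == "treat_none", ]
  expect_true(all(tn$net_benefit == 0))
  ta <- dca[dca$strategy == "treat_all", ]
  expect_equal(ta$net_benefit[ta$threshold_prob == 0.1],
               0.2 - 0.8 * (0.1 / 0.9), tolerance = 1e-12)
  expect_equal(ta$net_benefit[ta$threshold_prob == 0.1], 0.1111,
               tolerance = 1e-3)
  # perfect model: NB = F(t) at every threshold
  perfect <- as.numeric(rec$event == "krt")
  dca2 <- decision_curve(rec, scored_models = list(perfect = perfect),
                         pt_grid = seq(0.05, 0.9, 0.05))
  pm <- dca2[dca2$strategy == "perfect", ]
  expect_true(all(abs(pm$net_benefit - 0.2) < 1e-12))
  # net benefit never exceeds the overall CIF
  expect_true(all(dca2$net_benefit <= 0.2 + 1e-12))
  # a strategy referring nobody contributes NB = 0
  dca3 <- decision_curve(rec, fixed_rules = list(nobody = rep(FALSE, 10)),
                         pt_grid = c(0.1))
  expect_identical(dca3$net_benefit[dca3$strategy == "nobody"], 0)
  expect_error(decision_curve(rec, pt_grid = c(0, 0.5)), "0,1")
})
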