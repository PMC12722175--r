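uncensored_toy <- function() {
  # complete follow-up within the horizon: events early, non-events beyond
  rec_df(c(3000, 3000, 100, 150), c("censored", "censored", "krt", "krt"))
}

test_that("uncensored toy reduces to the empirical binary ROC", {
  rec <- uncensored_toy()
  scores <- c(0.1, 0.2, 0.3, 0.4)
  labels <- rec$event == "krt"
  roc <- cd_roc(rec, scores, 5)
  for (i in seq_len(nrow(roc))) {
    bp <- bf_binary_point(scores, labels, roc$threshold[i])
    expect_equal(roc$sensitivity[i], bp[["sens"]], tolerance = 1e-12)
    expect_equal(roc$specificity[i], bp[["spec"]], tolerance = 1e-12)
  }
  yo <- youden_optimal(roc)
  expect_identical(yo$threshold, 0.3)
  expect_equal(yo$J, 1, tolerance = 1e-12)
})

test_that("reduction holds on larger uncensored data with random scores", {
  set.seed(81)
  n <- 300
  lab <- runif(n) < 0.3
  time <- ifelse(lab, sample(50:1500, n, TRUE), 3000)
  rec <- rec_df(time, ifelse(lab, "krt", "censored"))
  scores <- round(runif(n), 2)
  roc <- cd_roc(rec, scores, 5)
  for (c in sample(unique(scores), 10)) {
    bp <- bf_binary_point(scores, lab, c)
    i <- which(roc$threshold == c)
    expect_equal(roc$sensitivity[i], bp[["sens"]], tolerance = 1e-12)
    expect_equal(roc$specificity[i], bp[["spec"]], tolerance = 1e-12)
  }
})

test_that("the curve has proper endpoints and monotone sweep", {
  set.seed(82)
  cfg <- recovery_config(1500, seed = 82, krt_rate = 0.05, death_rate = 0.05,
                         emigration_rate = 0.02)
  rec <- sim_records(cfg, horizon_years = 5)
  risks <- score_cohort(rec, kfre_published(), 5)
  roc <- cd_roc(rec, risks, 5)
  expect_equal(roc$sensitivity[1], 1, tolerance = 1e-12)
  expect_equal(roc$specificity[1], 0, tolerance = 1e-12)
  n <- nrow(roc)
  expect_equal(roc$sensitivity[n], 0, tolerance = 1e-12)
  expect_equal(roc$specificity[n], 1, tolerance = 1e-12)
  # under censoring the group-wise product-limit construction can wobble by
  # O(1/n); exact monotonicity is recovered in the uncensored reduction
  expect_true(all(diff(roc$sensitivity) <= 0.01))
  expect_true(all(diff(roc$specificity) >= -0.01))
  # uncensored data: exactly monotone
  lab <- rec$event == "krt" & rec$followup_days <= horizon_days(5)
  recu <- rec_df(ifelse(lab, 100, 3000), ifelse(lab, "krt", "censored"))
  rocu <- cd_roc(recu, risks, 5)
  expect_true(all(diff(rocu$sensitivity) <= 1e-12))
  expect_true(all(diff(rocu$specificity) >= -1e-12))
})

test_that("an uninformative score has AUC near one half and J near zero", {
  set.seed(83)
  n <- 4000
  lab <- runif(n) < 0.2
  rec <- rec_df(ifelse(lab, sample(50:1500, n, TRUE), 3000),
                ifelse(lab, "krt", "censored"))
  scores <- runif(n)
  roc <- cd_roc(rec, scores, 5, max_thresholds = 200)
  expect_lt(abs(roc_auc(roc) - 0.5), 0.03)
  expect_lt(youden_optimal(roc)$J, 0.08)
})

test_that("Youden ties break to the higher threshold and shifts carry over", {
  roc <- structure(
    data.frame(threshold = c(0.1, 0.2, 0.3),
               sensitivity = c(1, 0.9, 0.5),
               specificity = c(0.4, 0.5, 0.9)),
    class = c("roc_curve", "data.frame"))
  # J = 0.4 at both 0.2 and 0.3 -> pick 0.3
  expect_identical(youden_optimal(roc)$threshold, 0.3)
  # shifting all scores shifts the optimum, J unchanged
  rec <- uncensored_toy()
  scores <- c(0.1, 0.2, 0.3, 0.4)
  y1 <- youden_optimal(cd_roc(rec, scores, 5))
  y2 <- youden_optimal(cd_roc(rec, scores + 0.25, 5))
  expect_equal(y2$threshold, y1$threshold + 0.25, tolerance = 1e-12)
  expect_equal(y2$J, y1$J, tolerance = 1e-12)
})

test_that("matched comparison interpolates linearly with boundary flags", {
  roc <- structure(
    data.frame(threshold = c(0.6, 0.2),
               sensitivity = c(0.8, 1),
               specificity = c(0.9, 0.5)),
    class = c("roc_curve", "data.frame"))
  mc <- matched_comparison(roc, rule_sens = 0.9, rule_spec = 0.7)
  expect_equal(mc$sens_at_matched_spec, 0.9, tolerance = 1e-12)
  expect_equal(mc$spec_at_matched_sens, 0.7, tolerance = 1e-12)
  expect_false(mc$spec_boundary)
  # a rule point on the curve returns itself
  mc2 <- matched_comparison(roc, rule_sens = 0.8, rule_spec = 0.9)
  expect_equal(mc2$sens_at_matched_spec, 0.8, tolerance = 1e-12)
  expect_equal(mc2$spec_at_matched_sens, 0.9, tolerance = 1e-12)
  # outside the represented range -> boundary flag
  mc3 <- matched_comparison(roc, rule_sens = 0.5, rule_spec = 0.99)
  expect_true(mc3$spec_boundary)
  expect_error(matched_comparison(roc, 1.2, 0.5), "0,1")
})

test_that("a perfect-model ROC dominates any rule with lower specificity", {
  rec <- uncensored_toy()
  roc <- cd_roc(rec, c(0, 0, 1, 1), 5)
  mc <- matched_comparison(roc, rule_sens = 0.9, rule_spec = 0.7)
  expect_equal(mc$sens_at_matched_spec, 1, tolerance = 1e-12)
})
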