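#' Decile calibration table with competing-risk observed incidence
#'
#' Splits records into groups of (approximately) equal size by quantiles of
#' predicted risk, and compares the group mean predicted risk with the
#' observed Aalen-Johansen KRT cumulative incidence at the horizon, with a
#' pointwise log(-log) confidence interval. Records with identical predicted
#' risks stay in one group; if ties collapse quantile breaks the group count
#' is reduced with a warning. A sub-table re-splitting the lowest 20% of
#' predicted risk (the region most relevant for referral decisions) is
#' attached as attribute `"lowest20"`.
#'
#' @param records observation records with `followup_days`, `event`
#' @param risks predicted risks aligned with `records`
#' @param horizon_years horizon in years
#' @param n_groups number of risk groups (default 10)
#' @param lowest20 also compute the lowest-20% sub-table (default TRUE)
#' @return data frame of class `calibration_table` with columns `group`,
#'   `n`, `mean_pred`, `obs_cif`, `se`, `ci_lo`, `ci_hi`
#' @export
calibration_table <- function(records, risks, horizon_years = 5,
                              n_groups = 10, lowest20 = TRUE) {
  stopifnot(length(risks) == nrow(records))
  hd <- horizon_days(horizon_years)
  breaks <- unique(stats::quantile(risks, probs = seq(0, 1, 1 / n_groups),
                                   type = 7, names = FALSE))
  if (length(breaks) < 2) {
    warning("calibration_table: constant predicted risk; single group returned")
    grp <- factor(rep(1L, length(risks)))
  } else {
    if (length(breaks) - 1 < n_groups) {
      warning(sprintf(
        "calibration_table: ties reduced the group count from %d to %d",
        n_groups, length(breaks) - 1))
    }
    grp <- cut(risks, breaks, include.lowest = TRUE, labels = FALSE)
    grp <- factor(grp)
  }
  lv <- levels(grp)
  out <- do.call(rbind, lapply(seq_along(lv), function(g) {
    sel <- grp == lv[g]
    curve <- aalen_johansen(records[sel, , drop = FALSE])
    ci <- cif_ci_at(curve, hd, "krt")
    data.frame(group = g, n = sum(sel), mean_pred = mean(risks[sel]),
               obs_cif = ci[["est"]],
               se = sqrt(cif_var_at(curve, hd, "krt")),
               ci_lo = ci[["lo"]], ci_hi = ci[["hi"]])
  }))
  rownames(out) <- NULL
  attr(out, "horizon_years") <- horizon_years
  if (lowest20 && length(breaks) >= 2) {
    cut20 <- stats::quantile(risks, 0.2, type = 7, names = FALSE)
    sel20 <- risks <= cut20
    if (sum(sel20) >= n_groups && length(unique(risks[sel20])) > 1) {
      attr(out, "lowest20") <- calibration_table(
        records[sel20, , drop = FALSE], risks[sel20], horizon_years,
        n_groups, lowest20 = FALSE)
    }
  }
  class(out) <- c("calibration_table", class(out))
  out
}

#' Calibration slope of predicted risks against observed KRT hazard
#'
#' Cox regression of the KRT outcome (death treated as censoring) on the
#' model's linear predictor; a slope of 1 indicates that the spread of the
#' predictions matches the data.
#'
#' @param records observation records
#' @param lp linear predictors aligned with `records`
#' @return list with `slope` and `se`
#' @export
calibration_slope <- function(records, lp) {
  fit <- survival::coxph(
    survival::Surv(records$followup_days, records$event == "krt") ~ lp,
    ties = "efron")
  list(slope = unname(stats::coef(fit)),
       se = unname(sqrt(diag(stats::vcov(fit)))))
}
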