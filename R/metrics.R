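#' Truncated concordance index under competing risks
#'
#' Cause-specific C-index truncated at the horizon: usable pairs consist of
#' a KRT case (event at T_i within the horizon) and any record known to be
#' KRT-free at T_i - a record still under observation beyond T_i, or one
#' that died without KRT at or before T_i (death precludes KRT, so such
#' records are non-case controls). A pair is concordant when the case has
#' the higher predicted risk; risk ties count 1/2.
#'
#' @param records observation records with `followup_days`, `event`
#' @param risks predicted risks aligned with `records`
#' @param horizon_years truncation horizon in years
#' @return concordance in [0,1]
#' @export
c_index <- function(records, risks, horizon_years = 5) {
  stopifnot(length(risks) == nrow(records))
  hd <- horizon_days(horizon_years)
  time <- records$followup_days
  ev <- records$event
  cases <- which(ev == "krt" & time <= hd)
  if (length(cases) == 0) stop_input("c_index: no usable pairs (no cases)")
  conc <- ties <- npair <- 0
  is_death <- ev == "death"
  for (i in cases) {
    ctrl <- (time > time[i]) | (is_death & time <= time[i])
    ctrl[i] <- FALSE
    m <- sum(ctrl)
    if (m == 0) next
    conc <- conc + sum(risks[i] > risks[ctrl])
    ties <- ties + sum(risks[i] == risks[ctrl])
    npair <- npair + m
  }
  if (npair == 0) stop_input("c_index: no comparable pairs")
  (conc + 0.5 * ties) / npair
}

# Kaplan-Meier of the censoring distribution, with the convention that at
# tied times events precede censorings; returns a step function evaluator
# G(t) and its left limit G(t-).
censoring_km <- function(time, is_event) {
  ord <- order(time)
  t <- time[ord]
  e <- is_event[ord]
  grp <- cumsum(!duplicated(t))
  k <- max(grp)
  ut <- t[!duplicated(t)]
  d <- as.numeric(rowsum(as.numeric(e), grp))        # events at t
  c_ <- as.numeric(rowsum(as.numeric(!e), grp))      # censorings at t
  tot <- d + c_
  nrisk <- length(t) - c(0, cumsum(tot)[-k])
  denom <- nrisk - d                                 # events leave first
  g <- cumprod(ifelse(denom > 0, 1 - c_ / denom, 1))
  list(
    at = function(x) step_at(ut, g, x, zero = 1),
    at_left = function(x) step_at(ut, g, x - 1e-9, zero = 1))
}

#' IPCW Brier score at a horizon under competing risks
#'
#' Inverse-probability-of-censoring weighted squared error of the predicted
#' KRT risk at the horizon. Records with KRT by the horizon are cases
#' (target 1, weight 1/G(T-)); records under observation beyond the horizon
#' (target 0, weight 1/G(t)) and records that died without KRT by the
#' horizon (target 0, weight 1/G(T-)) are controls; records censored before
#' the horizon get weight 0. G is the Kaplan-Meier of the censoring
#' distribution. On uncensored data this is the mean squared error.
#'
#' @param records observation records
#' @param risks predicted risks in [0,1]
#' @param horizon_years horizon in years
#' @return Brier score (>= 0)
#' @export
brier_score <- function(records, risks, horizon_years = 5) {
  stopifnot(length(risks) == nrow(records))
  if (any(risks < 0 | risks > 1)) {
    stop_input("brier_score: risks must lie in [0,1]")
  }
  hd <- horizon_days(horizon_years)
  time <- records$followup_days
  ev <- records$event
  G <- censoring_km(time, ev != "censored")
  w <- numeric(nrow(records))
  resid <- numeric(nrow(records))
  case <- ev == "krt" & time <= hd
  death_ctrl <- ev == "death" & time <= hd
  late <- time > hd
  w[case] <- 1 / G$at_left(time[case])
  resid[case] <- (1 - risks[case])^2
  w[death_ctrl] <- 1 / G$at_left(time[death_ctrl])
  resid[death_ctrl] <- risks[death_ctrl]^2
  w[late] <- 1 / G$at(hd)
  resid[late] <- risks[late]^2
  bad <- !is.finite(w)
  if (any(bad)) {
    warning("brier_score: zero censoring-survival weight for some records; dropped")
    w[bad] <- 0
  }
  sum(w * resid) / nrow(records)
}
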