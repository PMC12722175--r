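# core product-limit bookkeeping; assumes nothing about sortedness.
# event codes: 0 censored, 1 krt, 2 death. At tied times events are
# processed before censorings (standard product-limit convention).
aj_core <- function(time, code) {
  ord <- order(time)
  t <- time[ord]
  cd <- code[ord]
  grp <- cumsum(!duplicated(t))
  k <- max(grp)
  ut <- t[!duplicated(t)]
  d1 <- as.numeric(rowsum(as.numeric(cd == 1L), grp))
  d2 <- as.numeric(rowsum(as.numeric(cd == 2L), grp))
  tot <- as.numeric(rowsum(rep(1, length(t)), grp))
  nrisk <- length(t) - c(0, cumsum(tot)[-k])
  de <- d1 + d2
  surv <- cumprod(1 - de / nrisk)
  sprev <- c(1, surv[-k])
  list(times = ut, n_risk = nrisk, d1 = d1, d2 = d2,
       n_censor = tot - de, surv = surv, sprev = sprev,
       cif1 = cumsum(sprev * d1 / nrisk),
       cif2 = cumsum(sprev * d2 / nrisk))
}

# variance of the cause-specific CIF (Marubini-Valsecchi form), evaluated
# at every event time via cumulative sums
aj_var <- function(core, dk, cif) {
  nr <- core$n_risk
  de <- core$d1 + core$d2
  a <- ifelse(nr > de, de / (nr * (nr - de)), 0)
  b <- core$sprev^2 * ((nr - dk) / nr) * (dk / nr^2)
  cc <- core$sprev * dk / nr^2
  A <- cumsum(a); Fa <- cumsum(cif * a); F2a <- cumsum(cif^2 * a)
  B <- cumsum(b); C <- cumsum(cc); FC <- cumsum(cif * cc)
  v <- cif^2 * A - 2 * cif * Fa + F2a + B - 2 * cif * C + 2 * FC
  pmax(v, 0)
}

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' Nonparametric estimator of the cumulative incidence function (CIF) of KRT
#' with death as a competing event:
#' \deqn{\hat F_k(t) = \sum_{t_i \le t} \hat S(t_i^-)\, d_{k,i}/n_i}
#' where S is the all-cause Kaplan-Meier. With no competing events the KRT
#' CIF reduces exactly to 1 - KM. At tied times events are processed before
#' censorings.
#'
#' @param records data frame with `followup_days` (> 0) and `event`
#'   (`"krt"`, `"death"`, `"censored"`)
#' @return object of class `cif_curve`: distinct event times, at-risk and
#'   per-cause event counts, overall survival, per-cause CIFs and variances
#' @export
aalen_johansen <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop_input("aalen_johansen: empty input")
  }
  if (any(records$followup_days < 0)) {
    stop_input("aalen_johansen: negative follow-up")
  }
  code <- match(records$event, c("censored", "krt", "death")) - 1L
  if (anyNA(code)) stop_input("aalen_johansen: unknown event label")
  core <- aj_core(records$followup_days, code)
  structure(
    list(times = core$times, n_risk = core$n_risk,
         n_event = cbind(krt = core$d1, death = core$d2),
         n_censor = core$n_censor, surv = core$surv,
         cif = cbind(krt = core$cif1, death = core$cif2),
         var = cbind(krt = aj_var(core, core$d1, core$cif1),
                     death = aj_var(core, core$d2, core$cif2))),
    class = "cif_curve")
}

step_at <- function(times, values, t, zero = 0) {
  idx <- findInterval(t, times)
  ifelse(idx == 0, zero, values[pmax(idx, 1)])
}

#' Evaluate a CIF curve (step function) at given times
#'
#' @param curve a `cif_curve` from [aalen_johansen()]
#' @param t times (same unit as the input follow-up)
#' @param cause `"krt"` or `"death"`
#' @return CIF values (right-continuous step function)
#' @export
cif_at <- function(curve, t, cause = "krt") {
  step_at(curve$times, curve$cif[, cause], t)
}

#' @rdname cif_at
#' @export
surv_at <- function(curve, t) {
  step_at(curve$times, curve$surv, t, zero = 1)
}

#' @rdname cif_at
#' @export
cif_var_at <- function(curve, t, cause = "krt") {
  step_at(curve$times, curve$var[, cause], t)
}

#' Pointwise confidence interval for a CIF on the log(-log) scale
#'
#' @param curve a `cif_curve`
#' @param t evaluation time
#' @param cause `"krt"` or `"death"`
#' @param level confidence level
#' @return named vector `c(est, lo, hi)`
#' @export
cif_ci_at <- function(curve, t, cause = "krt", level = 0.95) {
  f <- cif_at(curve, t, cause)
  v <- cif_var_at(curve, t, cause)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (is.na(f) || f <= 0 || f >= 1 || v <= 0) {
    return(c(est = f, lo = f, hi = f))
  }
  se_ll <- sqrt(v) / (f * abs(log(f)))
  lo <- f^exp(z * se_ll)
  hi <- f^exp(-z * se_ll)
  c(est = f, lo = min(lo, hi), hi = max(lo, hi))
}

#' @export
print.cif_curve <- function(x, ...) {
  k <- length(x$times)
  cat(sprintf("Aalen-Johansen curve: %d distinct times, final CIF krt=%.4f death=%.4f S=%.4f\n",
              k, x$cif[k, "krt"], x$cif[k, "death"], x$surv[k]))
  invisible(x)
}

#' Export a CIF curve as a tidy data frame
#'
#' @param curve a `cif_curve`
#' @param cause cause to export
#' @param level confidence level for the pointwise interval
#' @return data frame (time, cif, ci_lo, ci_hi, n_risk)
#' @export
cif_tidy <- function(curve, cause = "krt", level = 0.95) {
  ci <- t(vapply(curve$times, function(t) cif_ci_at(curve, t, cause, level),
                 numeric(3)))
  data.frame(time = curve$times, cif = curve$cif[, cause],
             ci_lo = ci[, "lo"], ci_hi = ci[, "hi"], n_risk = curve$n_risk)
}
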