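# fast KRT-CIF at a horizon for a subgroup (no object construction)
aj_cif_quick <- function(time, code, horizon) {
  if (length(time) == 0) return(0)
  core <- aj_core(time, code)
  step_at(core$times, core$cif1, horizon)
}

#' Cumulative/dynamic ROC curve under competing risks
#'
#' For each threshold c, referral-positive records are those with predicted
#' risk at or above c. Sensitivity and specificity at horizon t are built
#' from Aalen-Johansen CIFs so that death before KRT counts as "did not need
#' referral":
#' \deqn{Sens(c,t) = P(M \ge c)\, F_{\ge c}(t) / F(t)}
#' \deqn{Spec(c,t) = P(M < c)\, (1 - F_{< c}(t)) / (1 - F(t))}
#' with F the KRT CIF overall and within the score-defined groups. With
#' complete uncensored follow-up and no deaths this reduces exactly to the
#' empirical binary ROC.
#'
#' @param records observation records with `followup_days` and `event`
#' @param risks predicted risks aligned with `records`
#' @param horizon_years evaluation horizon (years)
#' @param thresholds optional explicit threshold grid; default all distinct
#'   risk values (exact Youden optimisation)
#' @param max_thresholds cap on the grid size; when the number of distinct
#'   risks exceeds it, an evenly spaced quantile grid is used instead
#' @return object of class `roc_curve`: data frame (threshold, sensitivity,
#'   specificity) with the horizon as attribute; includes -Inf/+Inf sentinel
#'   thresholds so the (1,0) and (0,1) endpoints are present
#' @export
cd_roc <- function(records, risks, horizon_years = 5, thresholds = NULL,
                   max_thresholds = Inf) {
  stopifnot(length(risks) == nrow(records))
  hd <- horizon_days(horizon_years)
  code <- match(records$event, c("censored", "krt", "death")) - 1L
  if (anyNA(code)) stop_input("cd_roc: unknown event label")
  ord <- order(records$followup_days)
  time <- records$followup_days[ord]
  code <- code[ord]
  r <- risks[ord]
  f_all <- aj_cif_quick(time, code, hd)
  if (f_all <= 0) stop_input("cd_roc: no KRT events by the horizon")
  if (is.null(thresholds)) {
    thresholds <- sort(unique(risks))
    if (length(thresholds) > max_thresholds) {
      thresholds <- sort(unique(stats::quantile(
        risks, probs = seq(0, 1, length.out = max_thresholds), type = 7,
        names = FALSE)))
    }
  } else {
    thresholds <- sort(unique(thresholds))
  }
  ths <- c(-Inf, thresholds, Inf)
  n <- length(time)
  sens <- spec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pos <- r >= ths[i]
    npos <- sum(pos)
    f_pos <- if (npos > 0) aj_cif_quick(time[pos], code[pos], hd) else 0
    f_neg <- if (npos < n) aj_cif_quick(time[!pos], code[!pos], hd) else 0
    sens[i] <- (npos / n) * f_pos / f_all
    spec[i] <- ((n - npos) / n) * (1 - f_neg) / (1 - f_all)
  }
  out <- data.frame(threshold = ths,
                    sensitivity = pmin(pmax(sens, 0), 1),
                    specificity = pmin(pmax(spec, 0), 1))
  attr(out, "horizon_years") <- horizon_years
  class(out) <- c("roc_curve", class(out))
  out
}

#' Area under a ROC curve (trapezoidal)
#'
#' @param roc a `roc_curve`
#' @return AUC in [0,1]
#' @export
roc_auc <- function(roc) {
  x <- 1 - roc$specificity
  y <- roc$sensitivity
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Youden-optimal threshold of a ROC curve
#'
#' Maximises J = sensitivity + specificity - 1 over the curve's thresholds;
#' ties are broken towards the higher threshold (fewer referrals).
#'
#' @param roc a `roc_curve`
#' @return list with `threshold`, `J`, `sensitivity`, `specificity`
#' @export
youden_optimal <- function(roc) {
  if (nrow(roc) == 0) stop_input("youden_optimal: empty curve")
  j <- roc$sensitivity + roc$specificity - 1
  best <- max(j)
  idx <- which(j >= best - 1e-12)
  pick <- idx[which.max(roc$threshold[idx])]
  list(threshold = roc$threshold[pick], J = j[pick],
       sensitivity = roc$sensitivity[pick],
       specificity = roc$specificity[pick])
}

# linear interpolation on a pre-sorted x grid with boundary flagging
interp_flag <- function(x, y, xout) {
  n <- length(x)
  if (xout <= x[1]) return(list(value = y[1], boundary = xout < x[1]))
  if (xout >= x[n]) return(list(value = y[n], boundary = xout > x[n]))
  list(value = stats::approx(x, y, xout = xout, ties = "ordered")$y,
       boundary = FALSE)
}

#' Compare a risk model's ROC with a fixed rule's operating point
#'
#' Linearly interpolates the model's ROC at the rule's specificity and
#' sensitivity, reporting the model's complementary coordinate and the
#' implied threshold at each matched point. Operating points outside the
#' curve's range are reported at the boundary with a flag.
#'
#' @param roc_model a `roc_curve`
#' @param rule_sens,rule_spec the fixed rule's sensitivity and specificity
#' @return list with `sens_at_matched_spec`, `threshold_at_matched_spec`,
#'   `spec_at_matched_sens`, `threshold_at_matched_sens`, and boundary flags
#' @export
matched_comparison <- function(roc_model, rule_sens, rule_spec) {
  if (any(c(rule_sens, rule_spec) < 0) || any(c(rule_sens, rule_spec) > 1)) {
    stop_input("matched_comparison: operating point must lie in [0,1]^2")
  }
  o <- order(roc_model$specificity, -roc_model$sensitivity)
  sp <- roc_model$specificity[o]
  se <- roc_model$sensitivity[o]
  th <- roc_model$threshold[o]
  a <- interp_flag(sp, se, rule_spec)
  a_th <- interp_flag(sp, th, rule_spec)
  o2 <- order(se)
  b <- interp_flag(se[o2], sp[o2], rule_sens)
  b_th <- interp_flag(se[o2], th[o2], rule_sens)
  list(sens_at_matched_spec = a$value,
       threshold_at_matched_spec = a_th$value,
       spec_at_matched_sens = b$value,
       threshold_at_matched_sens = b_th$value,
       spec_boundary = a$boundary, sens_boundary = b$boundary)
}
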