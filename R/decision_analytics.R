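#' Classification performance of a referral rule at a horizon
#'
#' Cross-tabulates referral decisions against observed KRT within the
#' horizon. Under the `raw_counts` policy a record is a case iff its event
#' is KRT within the horizon; records censored before the horizon and
#' records that died without KRT count as non-cases. Under `cif_weighted`
#' the expected number of cases per cell is `n_cell * CIF_cell(t)` with the
#' Aalen-Johansen KRT CIF inside the cell (censoring-robust); on uncensored
#' data the two policies coincide.
#'
#' @param records observation records with `followup_days`, `event`
#' @param referred logical referral decisions (from [evaluate_rule()])
#' @param horizon_years horizon in years
#' @param policy `"raw_counts"` (default) or `"cif_weighted"`
#' @return list of class `classification_counts` with `n_eligible`, `tp`,
#'   `fp`, `ppv`, `n_noneligible`, `tn`, `fn`, `npv`, `policy`,
#'   `horizon_years`, and `npv_degenerate` (TRUE when nobody is
#'   non-eligible, in which case NPV is reported as 1 by convention)
#' @export
classification_table <- function(records, referred, horizon_years = 5,
                                 policy = c("raw_counts", "cif_weighted")) {
  policy <- match.arg(policy)
  stopifnot(length(referred) == nrow(records))
  hd <- horizon_days(horizon_years)
  n_pos <- sum(referred)
  n_neg <- sum(!referred)
  cell_cases <- function(sel) {
    n <- sum(sel)
    if (n == 0) return(if (policy == "raw_counts") 0L else 0)
    if (policy == "raw_counts") {
      sum(records$event[sel] == "krt" & records$followup_days[sel] <= hd)
    } else {
      code <- match(records$event[sel], c("censored", "krt", "death")) - 1L
      n * aj_cif_quick(records$followup_days[sel], code, hd)
    }
  }
  tp <- cell_cases(referred)
  fn <- cell_cases(!referred)
  fp <- n_pos - tp
  tn <- n_neg - fn
  npv_degenerate <- n_neg == 0
  ppv_degenerate <- n_pos == 0
  structure(
    list(n_eligible = n_pos, tp = tp, fp = fp,
         ppv = if (ppv_degenerate) 1 else tp / n_pos,
         n_noneligible = n_neg, tn = tn, fn = fn,
         npv = if (npv_degenerate) 1 else tn / n_neg,
         policy = policy, horizon_years = horizon_years,
         npv_degenerate = npv_degenerate, ppv_degenerate = ppv_degenerate),
    class = "classification_counts")
}

#' @export
print.classification_counts <- function(x, ...) {
  cat(sprintf(
    "eligible %d (TP %.1f, FP %.1f, PPV %.3f) | non-eligible %d (TN %.1f, FN %.1f, NPV %.3f) [%s, %gy]\n",
    x$n_eligible, x$tp, x$fp, x$ppv, x$n_noneligible, x$tn, x$fn, x$npv,
    x$policy, x$horizon_years))
  invisible(x)
}

#' Reclassification matrix between two referral rules
#'
#' @param records observation records
#' @param old_referred,new_referred logical decisions of the two rules
#' @return 2x2 matrix of counts (rows: old no/yes; columns: new no/yes) with
#'   percentage attribute `"pct"`; cells sum to the record count
#' @export
reclassification_matrix <- function(records, old_referred, new_referred) {
  stopifnot(length(old_referred) == nrow(records),
            length(new_referred) == nrow(records))
  m <- table(factor(old_referred, levels = c(FALSE, TRUE),
                    labels = c("old_no", "old_yes")),
             factor(new_referred, levels = c(FALSE, TRUE),
                    labels = c("new_no", "new_yes")))
  m <- unclass(m)
  attr(m, "pct") <- 100 * m / max(nrow(records), 1L)
  m
}

#' Net reclassification improvement with competing-risk event probabilities
#'
#' Two-category NRI of a new referral rule against an old one. Event
#' probabilities per reclassification cell are Aalen-Johansen KRT CIFs at
#' the horizon (censoring-robust); with F_c the cell CIF, F the overall CIF,
#' n_c the cell size and "up" the old-no/new-yes cell:
#' \deqn{NRI^+ = (\sum_{up} n_c F_c - \sum_{down} n_c F_c) / (N F)}
#' \deqn{NRI^- = (\sum_{down} n_c (1-F_c) - \sum_{up} n_c (1-F_c)) / (N (1-F))}
#' On uncensored data this equals the classical binary two-category NRI
#' exactly. Swapping the rules flips the signs of all components.
#'
#' @param records observation records
#' @param old_referred,new_referred logical decisions
#' @param horizon_years horizon in years
#' @return list of class `nri_result` with `nri_events`, `nri_nonevents`,
#'   `nri_overall`, cell counts/CIFs and the horizon
#' @export
nri <- function(records, old_referred, new_referred, horizon_years = 5) {
  stopifnot(length(old_referred) == nrow(records),
            length(new_referred) == nrow(records))
  hd <- horizon_days(horizon_years)
  n <- nrow(records)
  code <- match(records$event, c("censored", "krt", "death")) - 1L
  f_all <- aj_cif_quick(records$followup_days, code, hd)
  if (f_all <= 0 || f_all >= 1) {
    stop_input("nri: overall event probability is %g; NRI undefined", f_all)
  }
  up <- !old_referred & new_referred
  down <- old_referred & !new_referred
  cell_f <- function(sel) {
    if (!any(sel)) return(0)
    aj_cif_quick(records$followup_days[sel], code[sel], hd)
  }
  f_up <- cell_f(up)
  f_down <- cell_f(down)
  n_up <- sum(up)
  n_down <- sum(down)
  nri_ev <- (n_up * f_up - n_down * f_down) / (n * f_all)
  nri_ne <- (n_down * (1 - f_down) - n_up * (1 - f_up)) / (n * (1 - f_all))
  structure(
    list(nri_events = nri_ev, nri_nonevents = nri_ne,
         nri_overall = nri_ev + nri_ne,
         cells = data.frame(cell = c("up", "down"), n = c(n_up, n_down),
                            cif = c(f_up, f_down)),
         overall_cif = f_all, horizon_years = horizon_years),
    class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("NRI at %gy: events %+0.4f, non-events %+0.4f, overall %+0.4f\n",
              x$horizon_years, x$nri_events, x$nri_nonevents, x$nri_overall))
  invisible(x)
}

#' Decision curve analysis with competing-risk event probabilities
#'
#' Net benefit of referral strategies across threshold probabilities p_t,
#' with the event probability among the referred estimated by the
#' Aalen-Johansen KRT CIF at the horizon:
#' \deqn{NB(p_t) = \frac{n_{pos}}{N} F_{pos}(t)
#'   - \frac{n_{pos}}{N} (1 - F_{pos}(t)) \frac{p_t}{1-p_t}.}
#' Risk models refer at risk >= p_t; fixed rules contribute a
#' threshold-independent classification. Treat-all
#' (`NB = F - (1-F) p_t/(1-p_t)`) and treat-none (`NB = 0`) references are
#' always included. Grid points where a strategy refers nobody get NB = 0.
#'
#' @param records observation records
#' @param scored_models named list of risk vectors (one per model), each
#'   aligned with `records`
#' @param fixed_rules named list of logical decision vectors
#' @param horizon_years horizon in years
#' @param pt_grid threshold probabilities in (0,1); default 0.005 to 0.30 in
#'   steps of 0.005 (covers the referral cutoffs usually discussed)
#' @return data frame of class `dca_curve`: `threshold_prob`, `strategy`,
#'   `net_benefit`
#' @export
decision_curve <- function(records, scored_models = list(),
                           fixed_rules = list(), horizon_years = 5,
                           pt_grid = seq(0.005, 0.30, by = 0.005)) {
  if (any(pt_grid <= 0 | pt_grid >= 1)) {
    stop_input("decision_curve: pt_grid must lie in (0,1)")
  }
  hd <- horizon_days(horizon_years)
  n <- nrow(records)
  code <- match(records$event, c("censored", "krt", "death")) - 1L
  f_all <- aj_cif_quick(records$followup_days, code, hd)
  nb_of <- function(pos, pt) {
    npos <- sum(pos)
    if (npos == 0) return(0)
    f_pos <- aj_cif_quick(records$followup_days[pos], code[pos], hd)
    (npos / n) * f_pos - (npos / n) * (1 - f_pos) * pt / (1 - pt)
  }
  rows <- list()
  rows[[1]] <- data.frame(threshold_prob = pt_grid, strategy = "treat_none",
                          net_benefit = 0)
  rows[[2]] <- data.frame(threshold_prob = pt_grid, strategy = "treat_all",
                          net_benefit = f_all - (1 - f_all) *
                            pt_grid / (1 - pt_grid))
  for (nm in names(scored_models)) {
    r <- scored_models[[nm]]
    stopifnot(length(r) == n)
    nb <- vapply(pt_grid, function(pt) nb_of(r >= pt, pt), numeric(1))
    rows[[length(rows) + 1]] <- data.frame(threshold_prob = pt_grid,
                                           strategy = nm, net_benefit = nb)
  }
  for (nm in names(fixed_rules)) {
    pos <- fixed_rules[[nm]]
    stopifnot(length(pos) == n)
    nb <- vapply(pt_grid, function(pt) nb_of(pos, pt), numeric(1))
    rows[[length(rows) + 1]] <- data.frame(threshold_prob = pt_grid,
                                           strategy = nm, net_benefit = nb)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "horizon_years") <- horizon_years
  attr(out, "overall_cif") <- f_all
  class(out) <- c("dca_curve", class(out))
  out
}
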