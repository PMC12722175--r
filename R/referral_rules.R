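#' Referral rules
#'
#' A referral rule is a deterministic predicate over observation records.
#' Three kinds are provided:
#' * [rule_kdigo2012()] - the 2012 KDIGO criteria: eGFR < 30, or ACR >= 300
#'   mg/g, or refractory hypertension (4+ antihypertensive classes in the
#'   prior 6 months);
#' * [rule_threshold()] - configurable disjunction-of-conjunctions over
#'   fixed thresholds of age, eGFR, ACR and antihypertensive count (for
#'   locally used criteria such as the Swedish referral thresholds);
#' * [rule_kfre()] - refer when the KFRE predicted risk reaches a cutoff.
#'
#' @name referral_rules
#' @return objects of class `referral_rule`; [evaluate_rule()] returns a
#'   logical vector of refer / not-refer decisions
NULL

new_rule <- function(name, kind, spec) {
  structure(list(name = name, kind = kind, spec = spec),
            class = "referral_rule")
}

#' @rdname referral_rules
#' @export
rule_kdigo2012 <- function() {
  new_rule("kdigo2012", "kdigo2012", NULL)
}

#' @param name rule label
#' @param clauses list of clauses; each clause is a named list with any of
#'   `egfr_below` (strict <), `acr_at_least` (>=), `age_below` (strict <),
#'   `age_at_least` (>=), `aht_at_least` (>= distinct antihypertensive
#'   classes). A clause fires when ALL its bounds hold; the rule fires when
#'   ANY clause fires. An empty clause list never refers.
#' @rdname referral_rules
#' @export
rule_threshold <- function(name, clauses) {
  allowed <- c("egfr_below", "acr_at_least", "age_below", "age_at_least",
               "aht_at_least")
  if (!is.list(clauses)) stop_input("rule_threshold: clauses must be a list")
  for (i in seq_along(clauses)) {
    cl <- clauses[[i]]
    if (!is.list(cl) || length(cl) == 0) {
      stop_input("rule_threshold: clause %d is empty or not a list", i)
    }
    bad <- setdiff(names(cl), allowed)
    if (length(bad)) {
      stop_input("rule_threshold: clause %d has unknown bound '%s'", i, bad[1])
    }
    if (any(!vapply(cl, function(v) is.numeric(v) && is.finite(v),
                    logical(1)))) {
      stop_input("rule_threshold: clause %d has a non-numeric bound", i)
    }
    if (!is.null(cl$age_at_least) && !is.null(cl$age_below) &&
        cl$age_at_least >= cl$age_below) {
      stop_input("rule_threshold: clause %d has an empty age interval", i)
    }
  }
  new_rule(name, "threshold", clauses)
}

#' @param model a [kfre_model()] for [rule_kfre()]
#' @param cutoff risk cutoff in (0,1]; 0 is allowed and refers everyone
#' @param horizon_years KFRE horizon for the cutoff
#' @param inclusive refer at risk >= cutoff (default); FALSE for strict >
#' @rdname referral_rules
#' @export
rule_kfre <- function(model, cutoff, horizon_years = 5, inclusive = TRUE) {
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff >= 1) {
    stop_input("rule_kfre: cutoff must lie in [0,1)")
  }
  new_rule(sprintf("%s_ge_%g_%gy", model$name, cutoff, horizon_years),
           "kfre",
           list(model = model, cutoff = cutoff,
                horizon_years = horizon_years, inclusive = inclusive))
}

#' Evaluate a referral rule on observation records
#'
#' @param rule a `referral_rule`
#' @param records observation records
#' @param risks optional precomputed risks for KFRE rules (skips rescoring)
#' @return logical vector: refer (TRUE) / not refer (FALSE)
#' @export
evaluate_rule <- function(rule, records, risks = NULL) {
  stopifnot(inherits(rule, "referral_rule"))
  n <- nrow(records)
  if (rule$kind == "kdigo2012") {
    return(records$egfr < 30 | records$acr_mgg >= 300 |
             records$n_antihypertensives_6mo >= 4)
  }
  if (rule$kind == "threshold") {
    out <- rep(FALSE, n)
    for (cl in rule$spec) {
      hit <- rep(TRUE, n)
      if (!is.null(cl$egfr_below)) hit <- hit & records$egfr < cl$egfr_below
      if (!is.null(cl$acr_at_least)) hit <- hit & records$acr_mgg >= cl$acr_at_least
      if (!is.null(cl$age_below)) hit <- hit & records$age_years < cl$age_below
      if (!is.null(cl$age_at_least)) hit <- hit & records$age_years >= cl$age_at_least
      if (!is.null(cl$aht_at_least)) {
        hit <- hit & records$n_antihypertensives_6mo >= cl$aht_at_least
      }
      out <- out | hit
    }
    return(out)
  }
  if (rule$kind == "kfre") {
    r <- risks %||% score_cohort(records, rule$spec$model,
                                 rule$spec$horizon_years)
    return(if (rule$spec$inclusive) r >= rule$spec$cutoff
           else r > rule$spec$cutoff)
  }
  stop_input("evaluate_rule: unknown rule kind '%s'", rule$kind)
}

#' @export
print.referral_rule <- function(x, ...) {
  cat("referral rule:", x$name, "(", x$kind, ")\n")
  invisible(x)
}

#' Read a threshold rule from a YAML config
#'
#' The YAML schema is `name:` plus `clauses:`, a list of bound maps (see
#' [rule_threshold()]). The packaged example
#' (`inst/extdata/swedish_rules_example.yaml`) carries PLACEHOLDER
#' thresholds in the structural style of Swedish referral criteria; it is
#' not an authoritative transcription and should be replaced with locally
#' valid thresholds before any applied use.
#'
#' @param path YAML path; default the packaged example
#' @return a `referral_rule`
#' @export
read_threshold_rule <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "swedish_rules_example.yaml",
                        package = "nephroref")
  }
  x <- yaml::read_yaml(path)
  if (is.null(x$name) || is.null(x$clauses)) {
    stop_input("read_threshold_rule: YAML must provide 'name' and 'clauses'")
  }
  rule_threshold(x$name, x$clauses)
}
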