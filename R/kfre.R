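#' Construct a KFRE-style risk model
#'
#' A four-variable KFRE model is a Cox-type index on transformed covariates
#' (age/10, male indicator, eGFR/5, ln ACR), each centred at the development
#' cohort mean, together with a baseline survival per prediction horizon:
#' \deqn{risk(t) = 1 - S_0(t)^{\exp(lp)}, \quad
#'       lp = \sum_i \beta_i (x_i - c_i).}
#'
#' @param name model label
#' @param coefficients numeric length-4 vector, order (age/10, male, eGFR/5,
#'   ln ACR)
#' @param centering numeric length-4 centering constants on the transformed
#'   scale
#' @param baseline_survival named numeric vector, names are horizons in years
#'   (e.g. `c("2" = 0.9878, "5" = 0.9240)`), values in (0,1)
#' @return an object of class `kfre_model`
#' @export
kfre_model <- function(name, coefficients, centering, baseline_survival) {
  coefficients <- as.numeric(coefficients)
  centering <- as.numeric(centering)
  if (length(coefficients) != 4L || any(!is.finite(coefficients))) {
    stop_input("kfre_model: coefficients must be 4 finite numbers")
  }
  if (length(centering) != 4L || any(!is.finite(centering))) {
    stop_input("kfre_model: centering must be 4 finite numbers")
  }
  s0 <- unlist(baseline_survival)
  if (is.null(names(s0)) || any(is.na(suppressWarnings(as.numeric(names(s0)))))) {
    stop_input("kfre_model: baseline_survival must be named by horizon (years)")
  }
  if (any(s0 <= 0) || any(s0 >= 1)) {
    stop_input("kfre_model: baseline survival must lie in (0,1)")
  }
  structure(
    list(name = name,
         coefficients = stats::setNames(coefficients,
                                        c("age10", "male", "egfr5", "lnacr")),
         centering = stats::setNames(centering,
                                     c("age10", "male", "egfr5", "lnacr")),
         baseline_survival = s0),
    class = "kfre_model")
}

#' @export
print.kfre_model <- function(x, ...) {
  cat("KFRE model:", x$name, "\n")
  cat("  coefficients:", paste(sprintf("%s=%.4f", names(x$coefficients),
                                       x$coefficients), collapse = ", "), "\n")
  cat("  baseline survival:",
      paste(sprintf("S0(%sy)=%.4f", names(x$baseline_survival),
                    x$baseline_survival), collapse = ", "), "\n")
  invisible(x)
}

#' Published four-variable KFRE models
#'
#' Coefficients and centering constants of the four-variable KFRE and the
#' per-horizon baseline survivals of the original (North American) and the
#' non-North American recalibrated variants. Constants are transcribed from
#' the original development and multinational recalibration publications
#' (externally sourced; verify against those sources before relying on the
#' golden values downstream).
#'
#' @param variant `"non_north_american"` (default) or `"original"`
#' @return a [kfre_model()]
#' @export
kfre_published <- function(variant = c("non_north_american", "original")) {
  variant <- match.arg(variant)
  s0 <- switch(variant,
    non_north_american = c("2" = 0.9878, "5" = 0.9240),
    original           = c("2" = 0.9832, "5" = 0.8996))
  kfre_model(
    name = paste0("kfre4_", variant),
    coefficients = c(-0.2201, 0.2467, -0.5567, 0.4510),
    centering = c(7.036, 0.5642, 7.222, 5.137),
    baseline_survival = s0)
}

# transformed, centred covariate matrix for the KFRE
kfre_design <- function(records, model) {
  need <- c("age_years", "is_male", "egfr", "acr_mgg")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop_input("records missing columns: %s", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(records$egfr)) || any(records$egfr <= 0)) {
    stop_input("kfre: eGFR must be positive")
  }
  if (any(!is.finite(records$acr_mgg)) || any(records$acr_mgg <= 0)) {
    stop_input("kfre: ACR must be positive (log undefined otherwise)")
  }
  z <- cbind(age10 = records$age_years / 10,
             male = as.numeric(records$is_male),
             egfr5 = records$egfr / 5,
             lnacr = log(records$acr_mgg))
  sweep(z, 2, model$centering, "-")
}

#' KFRE linear predictor
#'
#' @param records data frame of observation records with columns `age_years`,
#'   `is_male`, `egfr`, `acr_mgg`
#' @param model a [kfre_model()]
#' @return numeric vector of linear predictors (0 at the centering point)
#' @export
kfre_linear_predictor <- function(records, model = kfre_published()) {
  drop(kfre_design(records, model) %*% model$coefficients)
}

#' KFRE predicted risk at a horizon
#'
#' @param lp linear predictor(s) from [kfre_linear_predictor()]
#' @param model a [kfre_model()]
#' @param horizon_years horizon; must be present in the model's baseline
#'   survival map
#' @return risks in (0,1): `1 - S0^exp(lp)`
#' @export
kfre_risk <- function(lp, model = kfre_published(), horizon_years = 5) {
  key <- as.character(horizon_years)
  # tolerate numeric name mismatch like "5" vs "5.0"
  idx <- match(key, names(model$baseline_survival))
  if (is.na(idx)) {
    num <- suppressWarnings(as.numeric(names(model$baseline_survival)))
    idx <- match(as.numeric(horizon_years), num)
  }
  if (is.na(idx)) {
    stop_input("kfre_risk: model '%s' has no baseline survival for horizon %s",
               model$name, key)
  }
  s0 <- model$baseline_survival[[idx]]
  1 - s0^exp(lp)
}

#' Score every record of a cohort with a KFRE model
#'
#' Each record is scored independently, mirroring automatic reporting in an
#' electronic health record where the risk is recomputed at every test
#' without reference to earlier estimates.
#'
#' @param records observation records (see [kfre_linear_predictor()])
#' @param model a [kfre_model()]
#' @param horizon_years prediction horizon in years
#' @return numeric vector of predicted risks aligned with `records`
#' @export
score_cohort <- function(records, model = kfre_published(), horizon_years = 5) {
  kfre_risk(kfre_linear_predictor(records, model), model, horizon_years)
}

#' Read / write a KFRE model as JSON
#'
#' The JSON schema is `{name, coefficients, centering, baseline_survival}`;
#' coefficient order is (age/10, male, eGFR/5, ln ACR) and baseline survival
#' is keyed by horizon in years. Locally recalibrated variants (for example
#' coefficients published as an appendix of a validation study) can be
#' transcribed into such a file and loaded here.
#'
#' @param path JSON file path
#' @param model a [kfre_model()]
#' @return `read_kfre_model()` returns a [kfre_model()];
#'   `write_kfre_model()` returns `path` invisibly
#' @export
read_kfre_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kfre_model(x$name, x$coefficients, x$centering,
             unlist(x$baseline_survival))
}

#' @rdname read_kfre_model
#' @export
write_kfre_model <- function(model, path) {
  jsonlite::write_json(
    list(name = model$name,
         coefficients = unname(model$coefficients),
         centering = unname(model$centering),
         baseline_survival = as.list(model$baseline_survival)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
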