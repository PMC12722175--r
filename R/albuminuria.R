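#' Load an albuminuria conversion table
#'
#' The KFRE needs a urine albumin:creatinine ratio (ACR, mg/g). Registries
#' also hold protein:creatinine ratio (PCR) tests and semi-quantitative
#' dipstick tests; these are mapped to an ACR through a conversion table
#' keyed by modality and by sex/diabetes/hypertension strata (published
#' conversion equations stratify on those comorbidities).
#'
#' The table is a CSV with columns
#' `modality` (`pcr` or `dipstick`), `sex` (`male`, `female` or `any`),
#' `diabetes`, `hypertension` (`0`, `1` or `any`), `category` (dipstick
#' category, empty for PCR) and `value`: for dipstick rows the assigned ACR
#' in mg/g, for PCR rows the multiplicative factor ACR = value * PCR.
#'
#' The table shipped with the package
#' (`inst/extdata/albuminuria_fallback_synthetic.csv`) is a deliberately
#' crude, unstratified fallback (fixed per-category dipstick medians and a
#' fixed PCR factor) so the pipeline runs out of the box; it is synthetic
#' and NOT a transcription of any published conversion equation. Users with
#' access to published stratified coefficients should transcribe them into
#' a file with this schema and pass its path here.
#'
#' @param path CSV path; default the shipped fallback table
#' @return a validated `conversion_table` data frame
#' @export
load_conversion_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "albuminuria_fallback_synthetic.csv",
                        package = "nephroref")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("modality", "sex", "diabetes", "hypertension", "category", "value")
  if (!all(need %in% names(tab))) {
    stop_input("conversion table must have columns: %s",
               paste(need, collapse = ", "))
  }
  tab$value <- as.numeric(tab$value)
  validate_conversion_table(tab)
  class(tab) <- c("conversion_table", class(tab))
  tab
}

validate_conversion_table <- function(tab) {
  if (any(!is.finite(tab$value)) || any(tab$value <= 0)) {
    stop_input("conversion table: 'value' must be positive and finite")
  }
  bad <- tab$modality == "dipstick" & !(tab$category %in% DIPSTICK_LEVELS)
  if (any(bad)) {
    stop_input("conversion table: unknown dipstick category '%s'",
               tab$category[bad][1])
  }
  # dipstick ACR must be strictly increasing across categories per stratum
  dip <- tab[tab$modality == "dipstick", , drop = FALSE]
  strata <- interaction(dip$sex, dip$diabetes, dip$hypertension, drop = TRUE)
  for (s in levels(strata)) {
    rows <- dip[strata == s, , drop = FALSE]
    if (!all(DIPSTICK_LEVELS %in% rows$category)) {
      stop_input("conversion table: stratum %s missing dipstick categories", s)
    }
    v <- rows$value[match(DIPSTICK_LEVELS, rows$category)]
    if (any(diff(v) <= 0)) {
      stop_input(
        "conversion table: dipstick ACR not strictly increasing in stratum %s", s)
    }
  }
  if (!any(tab$modality == "pcr")) {
    stop_input("conversion table: no PCR rows")
  }
  invisible(tab)
}

match_stratum <- function(tab, modality, category, sex, diabetes, hypertension) {
  cand <- tab[tab$modality == modality, , drop = FALSE]
  if (modality == "dipstick") cand <- cand[cand$category == category, , drop = FALSE]
  sex_chr <- ifelse(sex, "male", "female")
  db <- as.character(as.integer(diabetes))
  ht <- as.character(as.integer(hypertension))
  hit <- cand[(cand$sex == sex_chr | cand$sex == "any") &
                (cand$diabetes == db | cand$diabetes == "any") &
                (cand$hypertension == ht | cand$hypertension == "any"), ,
              drop = FALSE]
  if (nrow(hit) == 0) {
    stop_input(
      "conversion table: no cell for modality=%s category=%s sex=%s diabetes=%s hypertension=%s",
      modality, category, sex_chr, db, ht)
  }
  # most specific match wins (fewest 'any' fields)
  spec <- rowSums(cbind(hit$sex != "any", hit$diabetes != "any",
                        hit$hypertension != "any"))
  hit$value[which.max(spec)]
}

#' Harmonize albuminuria tests to ACR in mg/g
#'
#' Native ACR passes through (with mg/mmol to mg/g conversion, factor 8.84,
#' when so tagged); PCR and dipstick tests map through the conversion table
#' using the record's sex, diabetes and hypertension strata.
#'
#' @param tests data frame with columns `analyte` (`acr`, `pcr`, `dipstick`),
#'   `value` (numeric, NA for dipstick), `unit` (`mg/g` or `mg/mmol` for
#'   quantitative tests) and `category` (dipstick category, NA otherwise)
#' @param diabetes,hypertension,is_male logical vectors recycled against
#'   `tests`
#' @param table a table from [load_conversion_table()]
#' @return numeric vector of ACR in mg/g
#' @export
harmonize_albuminuria <- function(tests, diabetes = FALSE, hypertension = FALSE,
                                  is_male = FALSE,
                                  table = load_conversion_table()) {
  n <- nrow(tests)
  diabetes <- rep_len(as.logical(diabetes), n)
  hypertension <- rep_len(as.logical(hypertension), n)
  is_male <- rep_len(as.logical(is_male), n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    analyte <- tests$analyte[i]
    if (analyte == "acr" || analyte == "pcr") {
      v <- tests$value[i]
      if (!is.finite(v) || v <= 0) {
        stop_input("harmonize_albuminuria: row %d has non-positive value", i)
      }
      unit <- tests$unit[i]
      if (identical(unit, "mg/mmol")) {
        v <- v * MGMMOL_TO_MGG
      } else if (!identical(unit, "mg/g")) {
        stop_input("harmonize_albuminuria: row %d has unknown unit '%s'",
                   i, unit)
      }
      out[i] <- if (analyte == "acr") v else {
        v * match_stratum(table, "pcr", "", is_male[i], diabetes[i],
                          hypertension[i])
      }
    } else if (analyte == "dipstick") {
      cat_i <- tests$category[i]
      if (!cat_i %in% DIPSTICK_LEVELS) {
        stop_input("harmonize_albuminuria: row %d has unknown dipstick category '%s'",
                   i, cat_i)
      }
      out[i] <- match_stratum(table, "dipstick", cat_i, is_male[i],
                              diabetes[i], hypertension[i])
    } else {
      stop_input("harmonize_albuminuria: row %d has unknown modality '%s'",
                 i, analyte)
    }
  }
  out
}

#' Convert between mg/mmol and mg/g
#'
#' @param x numeric values
#' @return converted values
#' @export
#' @rdname acr_units
acr_mgmmol_to_mgg <- function(x) x * MGMMOL_TO_MGG

#' @export
#' @rdname acr_units
acr_mgg_to_mgmmol <- function(x) x / MGMMOL_TO_MGG
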