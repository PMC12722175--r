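#' Pair creatinine with albuminuria tests
#'
#' Same-day tests pair on that day; otherwise each creatinine test pairs
#' with its nearest-in-time albuminuria test within `window_days` (ties go
#' to the earlier albuminuria test), and the index date is the later of the
#' two test dates. At most one record per creatinine test is produced
#' (default); `all_pairs = TRUE` instead cross-joins every albuminuria test
#' within the window of each creatinine test.
#'
#' @param creatinine_tests,albuminuria_tests data frames with `person_id`
#'   and `date` (Date); rows are referenced by position in the output
#' @param window_days pairing window (default 365, inclusive both directions)
#' @param all_pairs logical; emit all in-window pairs instead of nearest
#' @return data frame with `person_id`, `index_date`, `creat_row`, `alb_row`
#' @export
pair_tests <- function(creatinine_tests, albuminuria_tests,
                       window_days = 365, all_pairs = FALSE) {
  empty <- data.frame(person_id = integer(), index_date = as.Date(character()),
                      creat_row = integer(), alb_row = integer())
  if (nrow(creatinine_tests) == 0 || nrow(albuminuria_tests) == 0) {
    return(empty)
  }
  ord_a <- order(albuminuria_tests$person_id, albuminuria_tests$date)
  a_pid <- albuminuria_tests$person_id[ord_a]
  a_date <- as.integer(albuminuria_tests$date[ord_a])
  c_pid <- creatinine_tests$person_id
  c_date <- as.integer(creatinine_tests$date)

  if (all_pairs) {
    out <- vector("list", nrow(creatinine_tests))
    for (i in seq_along(c_pid)) {
      sel <- which(a_pid == c_pid[i] & abs(a_date - c_date[i]) <= window_days)
      if (length(sel)) {
        out[[i]] <- data.frame(
          person_id = c_pid[i],
          index_date = as.Date(pmax(a_date[sel], c_date[i]),
                               origin = "1970-01-01"),
          creat_row = i, alb_row = ord_a[sel])
      }
    }
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    return(if (is.null(res)) empty else res)
  }

  # nearest-in-time match via a combined (person, date) key
  scale <- max(a_date, c_date) - min(a_date, c_date) + 2 * window_days + 2L
  a_key <- as.numeric(a_pid) * scale + (a_date - min(a_date, c_date))
  c_key <- as.numeric(c_pid) * scale + (c_date - min(a_date, c_date))
  pos <- findInterval(c_key, a_key)            # last alb with key <= creat key
  left <- ifelse(pos >= 1 & pos <= length(a_key) & a_pid[pmax(pos, 1)] == c_pid,
                 pos, NA_integer_)
  posr <- pos + 1L
  right <- ifelse(posr <= length(a_key) & a_pid[pmin(posr, length(a_key))] == c_pid,
                  posr, NA_integer_)
  dl <- ifelse(is.na(left), Inf, c_date - a_date[pmax(left, 1)])
  dr <- ifelse(is.na(right), Inf, a_date[pmin(right, length(a_key))] - c_date)
  dl[dl > window_days] <- Inf
  dr[dr > window_days] <- Inf
  pick <- ifelse(dl <= dr, left, right)        # tie -> earlier albuminuria
  ok <- is.finite(pmin(dl, dr)) & !is.na(pick)
  if (!any(ok)) return(empty)
  pick <- pick[ok]
  data.frame(person_id = c_pid[ok],
             index_date = as.Date(pmax(c_date[ok], a_date[pick]),
                                  origin = "1970-01-01"),
             creat_row = which(ok), alb_row = ord_a[pick])
}

#' Count distinct antihypertensive classes in a lookback window
#'
#' Counts the DISTINCT drug classes dispensed in the half-open window
#' `(index - lookback_days, index]` for each record; repeated fills of one
#' class count once.
#'
#' @param dispensations data frame with `person_id`, `date`, `drug_class`
#' @param person_ids,index_dates vectors defining the records
#' @param lookback_days lookback length (default 183, about 6 months)
#' @return integer vector of distinct-class counts
#' @export
count_antihypertensives <- function(dispensations, person_ids, index_dates,
                                    lookback_days = 183) {
  n <- length(person_ids)
  out <- integer(n)
  if (nrow(dispensations) == 0 || n == 0) return(out)
  recs <- data.frame(rid = seq_len(n), person_id = person_ids,
                     index = as.integer(as.Date(index_dates)))
  dd <- data.frame(person_id = dispensations$person_id,
                   ddate = as.integer(dispensations$date),
                   drug_class = dispensations$drug_class)
  m <- merge(recs, dd, by = "person_id")
  if (nrow(m) == 0) return(out)
  keep <- m$ddate > m$index - lookback_days & m$ddate <= m$index
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) return(out)
  u <- unique(m[, c("rid", "drug_class")])
  tab <- table(factor(u$rid, levels = seq_len(n)))
  as.integer(tab)
}

#' Assign calendar-period labels
#'
#' Splits a study window into equal-width periods (default tertiles) and
#' labels each index date by the period it falls in.
#'
#' @param index_dates Date vector
#' @param study_start,study_end window bounds
#' @param n_periods number of equal-width periods
#' @return character labels `"period1"`, ...
#' @export
assign_calendar_period <- function(index_dates, study_start, study_end,
                                   n_periods = 3) {
  brk <- seq(as.numeric(as_date(study_start)),
             as.numeric(as_date(study_end)) + 1, length.out = n_periods + 1)
  idx <- findInterval(as.numeric(as.Date(index_dates)), brk,
                      rightmost.closed = TRUE, all.inside = TRUE)
  paste0("period", idx)
}

#' Build KFRE-evaluable observation records from raw tables
#'
#' Pairs tests, computes eGFR (revised Lund-Malmo) and harmonized ACR,
#' attaches comorbidity flags, the 6-month distinct antihypertensive-class
#' count and a calendar-period label. Follow-up and events are attached
#' separately by [attach_followup()].
#'
#' @param tables list with `persons`, `lab_tests`, `dispensations` (and
#'   optionally `outcomes`), as produced by [simulate_cohort()] or
#'   [read_cohort_tables()]
#' @param window_days pairing window for [pair_tests()]
#' @param conversion_table albuminuria conversion table
#' @param all_pairs pairing mode, see [pair_tests()]
#' @param lookback_days antihypertensive lookback
#' @param study_start,study_end window for calendar periods (defaults to the
#'   observed index-date range)
#' @return data frame of observation records
#' @export
build_observations <- function(tables, window_days = 365,
                               conversion_table = load_conversion_table(),
                               all_pairs = FALSE, lookback_days = 183,
                               study_start = NULL, study_end = NULL) {
  lt <- tables$lab_tests
  creat <- lt[lt$analyte == "creatinine", , drop = FALSE]
  alb <- lt[lt$analyte %in% c("acr", "pcr", "dipstick"), , drop = FALSE]
  pairs <- pair_tests(creat, alb, window_days, all_pairs)
  if (nrow(pairs) == 0) {
    return(data.frame(person_id = integer(),
                      index_date = as.Date(character()),
                      age_years = numeric(), is_male = logical(),
                      egfr = numeric(), acr_mgg = numeric(),
                      albuminuria_source = character(), diabetes = logical(),
                      hypertension = logical(),
                      n_antihypertensives_6mo = integer(),
                      calendar_period = character()))
  }
  p <- tables$persons
  pi <- match(pairs$person_id, p$person_id)
  if (anyNA(pi)) stop_input("build_observations: record references unknown person")
  is_male <- p$sex[pi] == "male"
  diabetes <- as.logical(p$diabetes[pi])
  hypertension <- as.logical(p$hypertension[pi])
  age <- as.numeric(pairs$index_date - p$birth_date[pi]) / DAYS_PER_YEAR
  egfr <- egfr_rlm(creat$value[pairs$creat_row], age, is_male)
  alb_rows <- alb[pairs$alb_row, , drop = FALSE]
  acr <- harmonize_albuminuria(alb_rows, diabetes, hypertension, is_male,
                               conversion_table)
  n_aht <- count_antihypertensives(tables$dispensations, pairs$person_id,
                                   pairs$index_date, lookback_days)
  ss <- study_start %||% min(pairs$index_date)
  se <- study_end %||% max(pairs$index_date)
  rec <- data.frame(person_id = pairs$person_id,
                    index_date = pairs$index_date,
                    age_years = age, is_male = is_male, egfr = egfr,
                    acr_mgg = acr,
                    albuminuria_source = alb_rows$analyte,
                    diabetes = diabetes, hypertension = hypertension,
                    n_antihypertensives_6mo = n_aht,
                    calendar_period = assign_calendar_period(
                      pairs$index_date, ss, se))
  rec <- rec[order(rec$person_id, rec$index_date), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Apply cohort entry exclusions
#'
#' A person is dropped entirely when, at their FIRST record, eGFR >= 60,
#' KRT had already started, or death occurred within 1 day of the index.
#' Surviving persons keep all their records (later records with eGFR >= 60
#' are retained by default; `drop_later_ge60 = TRUE` applies the stricter
#' per-record filter). Exclusion counts (persons, by first matching reason)
#' are returned alongside the records.
#'
#' @param records observation records from [build_observations()]
#' @param outcomes outcomes table (`person_id`, `krt_date`, `death_date`,
#'   `emigration_date`)
#' @param drop_later_ge60 also drop later records with eGFR >= 60
#' @return list with `records` (retained) and `exclusions` (named counts)
#' @export
apply_cohort_exclusions <- function(records, outcomes,
                                    drop_later_ge60 = FALSE) {
  if (nrow(records) == 0) {
    return(list(records = records,
                exclusions = c(egfr_ge60 = 0L, prevalent_krt = 0L,
                               early_death = 0L, persons_excluded = 0L)))
  }
  oi <- match(records$person_id, outcomes$person_id)
  if (anyNA(oi)) stop_input("apply_cohort_exclusions: unknown person in records")
  ord <- order(records$person_id, records$index_date)
  first <- ord[!duplicated(records$person_id[ord])]
  pid <- records$person_id[first]
  o <- outcomes[match(pid, outcomes$person_id), ]
  idx <- records$index_date[first]
  ex_egfr <- records$egfr[first] >= 60
  ex_krt <- !is.na(o$krt_date) & o$krt_date <= idx
  ex_death <- !is.na(o$death_date) & o$death_date <= idx + 1
  reason <- ifelse(ex_egfr, "egfr_ge60",
                   ifelse(ex_krt, "prevalent_krt",
                          ifelse(ex_death, "early_death", NA)))
  drop_pid <- pid[!is.na(reason)]
  keep <- !(records$person_id %in% drop_pid)
  out <- records[keep, , drop = FALSE]
  if (drop_later_ge60) out <- out[out$egfr < 60, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       exclusions = c(egfr_ge60 = sum(reason == "egfr_ge60", na.rm = TRUE),
                      prevalent_krt = sum(reason == "prevalent_krt",
                                          na.rm = TRUE),
                      early_death = sum(reason == "early_death", na.rm = TRUE),
                      persons_excluded = length(drop_pid)))
}

#' Attach follow-up time and event type to records
#'
#' Follow-up runs from the index date to the first of KRT, death, emigration,
#' the administrative end of data collection, or the horizon boundary
#' (`floor(365.25 * horizon_years)` days after index). The event label is
#' `"krt"` or `"death"` if that outcome hit first (KRT beyond the horizon is
#' censored at the horizon), else `"censored"`.
#'
#' @param records observation records
#' @param outcomes outcomes table
#' @param admin_end administrative censoring date (end of data collection)
#' @param horizon_years follow-up horizon in years
#' @return `records` with `followup_days` and `event` columns added
#' @export
attach_followup <- function(records, outcomes, admin_end, horizon_years = 5) {
  admin_end <- as_date(admin_end)
  if (nrow(records) == 0) {
    records$followup_days <- numeric(0)
    records$event <- character(0)
    return(records)
  }
  o <- outcomes[match(records$person_id, outcomes$person_id), ]
  idx <- records$index_date
  for (col in c("krt_date", "death_date", "emigration_date")) {
    bad <- !is.na(o[[col]]) & o[[col]] < idx
    if (any(bad)) {
      stop_input("attach_followup: %s before index date for person %s",
                 col, records$person_id[bad][1])
    }
  }
  hb <- idx + horizon_days(horizon_years)
  inf_date <- as.Date(Inf, origin = "1970-01-01")
  krt <- ifelse(is.na(o$krt_date), Inf, as.numeric(o$krt_date))
  death <- ifelse(is.na(o$death_date), Inf, as.numeric(o$death_date))
  cens <- pmin(ifelse(is.na(o$emigration_date), Inf,
                      as.numeric(o$emigration_date)),
               as.numeric(admin_end), as.numeric(hb))
  end <- pmin(krt, death, cens)
  event <- ifelse(krt == end, "krt", ifelse(death == end, "death",
                                            "censored"))
  records$followup_days <- end - as.numeric(idx)
  records$event <- event
  records
}

#' Sensitivity-analysis subsets of a record set
#'
#' @param records observation records
#' @param mode `"one_random_per_person"` (uniform draw per person, seeded),
#'   `"acr_only"` (keep quantitative albuminuria: native ACR and converted
#'   PCR; drop dipstick-based records), or `"period"` (keep records whose
#'   `calendar_period` equals `period`)
#' @param seed RNG seed for the random-observation mode
#' @param period period label for `mode = "period"`
#' @return the subset, a data frame
#' @export
subset_for_sensitivity <- function(records,
                                   mode = c("one_random_per_person",
                                            "acr_only", "period"),
                                   seed = 1L, period = NULL) {
  mode <- match.arg(mode)
  if (mode == "acr_only") {
    out <- records[records$albuminuria_source %in% c("acr", "pcr"), ,
                   drop = FALSE]
  } else if (mode == "period") {
    if (is.null(period)) stop_input("subset_for_sensitivity: period label required")
    out <- records[records$calendar_period == period, , drop = FALSE]
  } else {
    out <- with_seed(seed, {
      ids <- unique(records$person_id)
      pick <- vapply(split(seq_len(nrow(records)), records$person_id),
                     function(ix) ix[sample.int(length(ix), 1L)], integer(1))
      records[sort(pick[as.character(ids)]), , drop = FALSE]
    })
  }
  rownames(out) <- NULL
  out
}
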