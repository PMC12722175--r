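#' Competing-risk sensitivity/specificity of a fixed classification
#'
#' Operating point of a referral decision vector at a horizon using the same
#' Aalen-Johansen construction as [cd_roc()].
#'
#' @param records observation records
#' @param referred logical decisions
#' @param horizon_years horizon in years
#' @return named vector `c(sensitivity, specificity)`
#' @export
sens_spec_cr <- function(records, referred, horizon_years = 5) {
  hd <- horizon_days(horizon_years)
  code <- match(records$event, c("censored", "krt", "death")) - 1L
  n <- nrow(records)
  f_all <- aj_cif_quick(records$followup_days, code, hd)
  if (f_all <= 0) stop_input("sens_spec_cr: no KRT events by the horizon")
  npos <- sum(referred)
  f_pos <- if (npos > 0) {
    aj_cif_quick(records$followup_days[referred], code[referred], hd)
  } else 0
  f_neg <- if (npos < n) {
    aj_cif_quick(records$followup_days[!referred], code[!referred], hd)
  } else 0
  c(sensitivity = min(max((npos / n) * f_pos / f_all, 0), 1),
    specificity = min(max(((n - npos) / n) * (1 - f_neg) / (1 - f_all), 0), 1))
}

#' Operating-characteristics summary of referral strategies
#'
#' One row per risk model x cutoff and per fixed rule: referral fraction,
#' competing-risk sensitivity/specificity, raw-count PPV/NPV, and the
#' model's Youden-optimal cutoff.
#'
#' @param records observation records
#' @param scored_models named list of risk vectors
#' @param fixed_rules named list of logical decision vectors
#' @param cutoffs risk cutoffs applied to every model
#' @param horizon_years horizon in years
#' @param rocs optional named list of precomputed `roc_curve`s per model
#' @param max_thresholds passed to [cd_roc()] when curves are not supplied
#' @return data frame, one row per strategy
#' @export
compare_models_report <- function(records, scored_models, fixed_rules,
                                  cutoffs = c(0.03, 0.05, 0.15),
                                  horizon_years = 5, rocs = NULL,
                                  max_thresholds = 512) {
  rows <- list()
  for (nm in names(scored_models)) {
    r <- scored_models[[nm]]
    roc <- if (!is.null(rocs) && !is.null(rocs[[nm]])) rocs[[nm]] else
      cd_roc(records, r, horizon_years, max_thresholds = max_thresholds)
    yo <- youden_optimal(roc)
    for (cu in cutoffs) {
      pos <- r >= cu
      ss <- sens_spec_cr(records, pos, horizon_years)
      cl <- classification_table(records, pos, horizon_years)
      rows[[length(rows) + 1]] <- data.frame(
        strategy = nm, type = "kfre", cutoff = cu,
        referral_fraction = mean(pos),
        sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]],
        ppv = cl$ppv, npv = cl$npv,
        youden_threshold = yo$threshold, youden_J = yo$J)
    }
  }
  for (nm in names(fixed_rules)) {
    pos <- fixed_rules[[nm]]
    ss <- sens_spec_cr(records, pos, horizon_years)
    cl <- classification_table(records, pos, horizon_years)
    rows[[length(rows) + 1]] <- data.frame(
      strategy = nm, type = "rule", cutoff = NA_real_,
      referral_fraction = mean(pos),
      sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]],
      ppv = cl$ppv, npv = cl$npv,
      youden_threshold = NA_real_, youden_J = NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration of an end-to-end pipeline run
#'
#' @param sim a [sim_config()] to simulate input tables, or NULL when
#'   `cohort_dir` is given
#' @param cohort_dir directory holding the four cohort CSVs (alternative to
#'   `sim`)
#' @param out_dir output directory for reports
#' @param admin_end administrative end of data collection (default the
#'   simulation's `study_end`; required with `cohort_dir`)
#' @param horizons prediction horizons in years (first entries are fitted in
#'   recalibration); the evaluation horizon is `max(horizons)`
#' @param models character subset of `c("published", "original",
#'   "recalibrated")` and/or paths to KFRE model JSON files
#' @param rules named list of `referral_rule` objects (at least one)
#' @param cutoffs KFRE referral cutoffs in (0,1)
#' @param sensitivity_modes subset of `c("one_random_per_person",
#'   "acr_only", "period")`
#' @param seed integer master seed for the run
#' @param window_days,lookback_days observation-builder settings
#' @param conversion_table_path optional albuminuria conversion table CSV
#' @param max_thresholds ROC grid cap for large cohorts
#' @param min_recal_events minimum KRT events required for recalibration
#' @return validated `run_config`
#' @export
run_config <- function(sim = NULL, cohort_dir = NULL, out_dir,
                       admin_end = NULL,
                       horizons = c(2, 5),
                       models = c("published", "recalibrated"),
                       rules = list(kdigo2012 = rule_kdigo2012(),
                                    swedish_example = read_threshold_rule()),
                       cutoffs = c(0.03, 0.05, 0.09, 0.15),
                       sensitivity_modes = character(),
                       seed = 1L,
                       window_days = 365, lookback_days = 183,
                       conversion_table_path = NULL,
                       max_thresholds = 512,
                       min_recal_events = 50) {
  if (is.null(sim) == is.null(cohort_dir)) {
    stop_input("run_config: exactly one of 'sim' or 'cohort_dir' is required")
  }
  if (length(models) == 0) stop_input("run_config: at least one model required")
  if (length(rules) == 0) stop_input("run_config: at least one rule required")
  if (!all(vapply(rules, inherits, logical(1), "referral_rule"))) {
    stop_input("run_config: rules must be referral_rule objects")
  }
  if (is.null(names(rules)) || any(names(rules) == "")) {
    stop_input("run_config: rules must be named")
  }
  if (any(cutoffs <= 0 | cutoffs >= 1)) {
    stop_input("run_config: cutoffs must lie in (0,1)")
  }
  if (is.null(admin_end)) {
    if (is.null(sim)) stop_input("run_config: admin_end required with cohort_dir")
    admin_end <- sim$study_end
  }
  bad <- setdiff(sensitivity_modes,
                 c("one_random_per_person", "acr_only", "period"))
  if (length(bad)) stop_input("run_config: unknown sensitivity mode '%s'", bad[1])
  structure(list(sim = sim, cohort_dir = cohort_dir, out_dir = out_dir,
                 admin_end = as_date(admin_end), horizons = sort(horizons),
                 models = models, rules = rules, cutoffs = sort(cutoffs),
                 sensitivity_modes = sensitivity_modes,
                 seed = as.integer(seed),
                 window_days = window_days, lookback_days = lookback_days,
                 conversion_table_path = conversion_table_path,
                 max_thresholds = max_thresholds,
                 min_recal_events = min_recal_events),
            class = "run_config")
}

manifest_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(utils::capture.output(utils::str(obj)), collapse = "\n"),
             tmp)
  unname(tools::md5sum(tmp))
}

write_report_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# run %s", hash), con)
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline report CSV (skipping the manifest-hash comment line)
#'
#' @param path CSV path
#' @return data frame
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a run configuration from YAML
#'
#' The YAML may contain `sim:` (arguments to [sim_config()]) or
#' `cohort_dir:`, plus any of `horizons`, `models`, `cutoffs`,
#' `sensitivity_modes`, `admin_end`, `seed`, `window_days`, `lookback_days`,
#' `max_thresholds`, `min_recal_events`, and `rules:` as a map from rule
#' name to either `kdigo2012: true` or a threshold-rule YAML path.
#'
#' @param path YAML path
#' @param out_dir output directory (overrides any `out_dir` in the file)
#' @param seed optional seed override
#' @return a [run_config()]
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  x <- yaml::read_yaml(path)
  args <- x
  if (!is.null(x$sim)) args$sim <- do.call(sim_config, x$sim)
  if (!is.null(x$rules)) {
    args$rules <- lapply(x$rules, function(spec) {
      if (isTRUE(spec) || identical(spec, "kdigo2012")) rule_kdigo2012()
      else read_threshold_rule(spec)
    })
    names(args$rules) <- names(x$rules)
  }
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (!is.null(seed)) args$seed <- seed
  do.call(run_config, args)
}

#' Run the full referral-modelling pipeline
#'
#' simulate (or load) -> harmonize -> build observations -> exclusions ->
#' follow-up -> score models (with optional local recalibration) ->
#' competing-risk evaluation -> decision analytics -> tabular reports.
#' All randomness derives from the run seed; identical configs and seeds
#' give identical outputs.
#'
#' @param config a [run_config()]
#' @return (invisibly) list with the records, models, risks, reports and the
#'   output directory
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    tables <- simulate_cohort(sim)
  } else {
    tables <- read_cohort_tables(config$cohort_dir)
  }
  conv <- load_conversion_table(config$conversion_table_path)

  # ---- observation records ------------------------------------------------
  cand <- build_observations(tables, window_days = config$window_days,
                             conversion_table = conv,
                             lookback_days = config$lookback_days)
  exq <- apply_cohort_exclusions(cand, tables$outcomes)
  records <- exq$records
  if (nrow(records) == 0) stop_input("run_pipeline: no records after exclusions")
  # full follow-up (to administrative end) for model fitting
  rec_full <- attach_followup(records, tables$outcomes, config$admin_end,
                              horizon_years = 200)
  rec_full <- rec_full[rec_full$followup_days > 0, , drop = FALSE]
  h_eval <- max(config$horizons)
  rec <- attach_followup(rec_full, tables$outcomes, config$admin_end,
                         horizon_years = h_eval)

  # ---- models -------------------------------------------------------------
  models <- list()
  for (m in config$models) {
    if (identical(m, "published")) {
      models$published <- kfre_published("non_north_american")
    } else if (identical(m, "original")) {
      models$original <- kfre_published("original")
    } else if (identical(m, "recalibrated")) {
      recal <- fit_recalibration(rec_full, horizon_years = config$horizons,
                                 min_events = config$min_recal_events)
      models$recalibrated <- recal$model
    } else {
      mod <- read_kfre_model(m)
      models[[mod$name]] <- mod
    }
  }

  scored <- lapply(models, function(m) score_cohort(rec, m, h_eval))
  rule_dec <- lapply(config$rules, evaluate_rule, records = rec)

  # ---- evaluation ---------------------------------------------------------
  hash <- manifest_hash(list(seed = config$seed, horizons = config$horizons,
                             models = config$models,
                             rules = names(config$rules),
                             cutoffs = config$cutoffs,
                             n_records = nrow(rec)))
  out <- function(f) file.path(config$out_dir, f)

  scored_df <- cbind(rec,
                     stats::setNames(as.data.frame(scored),
                                     paste0("risk_", names(scored))),
                     stats::setNames(as.data.frame(rule_dec),
                                     paste0("refer_", names(rule_dec))))
  write_report_csv(scored_df, out("observations_scored.csv"), hash)
  jsonlite::write_json(as.list(exq$exclusions), out("exclusions.json"),
                       auto_unbox = TRUE)

  rocs <- lapply(scored, function(r) {
    cd_roc(rec, r, h_eval, max_thresholds = config$max_thresholds)
  })
  youden <- lapply(rocs, youden_optimal)
  for (nm in names(rocs)) {
    write_report_csv(as.data.frame(rocs[[nm]]),
                     out(sprintf("roc_%s.csv", nm)), hash)
    cal <- calibration_table(rec, scored[[nm]], h_eval)
    write_report_csv(as.data.frame(cal),
                     out(sprintf("calibration_%s.csv", nm)), hash)
    low <- attr(cal, "lowest20")
    if (!is.null(low)) {
      write_report_csv(as.data.frame(low),
                       out(sprintf("calibration_%s_lowest20.csv", nm)), hash)
    }
  }
  write_report_csv(
    data.frame(model = names(youden),
               threshold = vapply(youden, `[[`, numeric(1), "threshold"),
               J = vapply(youden, `[[`, numeric(1), "J"),
               sensitivity = vapply(youden, `[[`, numeric(1), "sensitivity"),
               specificity = vapply(youden, `[[`, numeric(1), "specificity")),
    out("youden.csv"), hash)

  discrimination <- data.frame(
    model = names(scored),
    c_index = vapply(scored, function(r) c_index(rec, r, h_eval), numeric(1)),
    brier = vapply(scored, function(r) brier_score(rec, r, h_eval),
                   numeric(1)),
    auc = vapply(rocs, roc_auc, numeric(1)))
  write_report_csv(discrimination, out("discrimination.csv"), hash)

  operating <- compare_models_report(rec, scored, rule_dec,
                                     cutoffs = config$cutoffs,
                                     horizon_years = h_eval, rocs = rocs)
  write_report_csv(operating, out("report_operating.csv"), hash)

  # classification (Table-3 style), reclassification + NRI (Table-4/Fig-2)
  cls_rows <- list()
  recl_rows <- list()
  nri_rows <- list()
  for (nm in names(scored)) {
    for (cu in config$cutoffs) {
      pos <- scored[[nm]] >= cu
      cl <- classification_table(rec, pos, h_eval)
      cls_rows[[length(cls_rows) + 1]] <- data.frame(
        strategy = sprintf("%s@%g", nm, cu),
        n_eligible = cl$n_eligible, tp = cl$tp, fp = cl$fp, ppv = cl$ppv,
        n_noneligible = cl$n_noneligible, tn = cl$tn, fn = cl$fn,
        npv = cl$npv)
      for (rn in names(rule_dec)) {
        m <- reclassification_matrix(rec, rule_dec[[rn]], pos)
        recl_rows[[length(recl_rows) + 1]] <- data.frame(
          old_rule = rn, new_rule = sprintf("%s@%g", nm, cu),
          old_no_new_no = m["old_no", "new_no"],
          old_no_new_yes = m["old_no", "new_yes"],
          old_yes_new_no = m["old_yes", "new_no"],
          old_yes_new_yes = m["old_yes", "new_yes"])
        nr <- nri(rec, rule_dec[[rn]], pos, h_eval)
        nri_rows[[length(nri_rows) + 1]] <- data.frame(
          old_rule = rn, new_rule = sprintf("%s@%g", nm, cu),
          nri_events = nr$nri_events, nri_nonevents = nr$nri_nonevents,
          nri_overall = nr$nri_overall)
      }
    }
  }
  for (rn in names(rule_dec)) {
    cl <- classification_table(rec, rule_dec[[rn]], h_eval)
    cls_rows[[length(cls_rows) + 1]] <- data.frame(
      strategy = rn, n_eligible = cl$n_eligible, tp = cl$tp, fp = cl$fp,
      ppv = cl$ppv, n_noneligible = cl$n_noneligible, tn = cl$tn,
      fn = cl$fn, npv = cl$npv)
  }
  write_report_csv(do.call(rbind, cls_rows), out("report_classification.csv"),
                   hash)
  write_report_csv(do.call(rbind, recl_rows),
                   out("report_reclassification.csv"), hash)
  write_report_csv(do.call(rbind, nri_rows), out("report_nri.csv"), hash)

  dca <- decision_curve(rec, scored, rule_dec, h_eval)
  write_report_csv(as.data.frame(dca), out("dca.csv"), hash)

  # matched sensitivity/specificity comparisons against each fixed rule
  match_rows <- list()
  for (nm in names(rocs)) {
    for (rn in names(rule_dec)) {
      ss <- sens_spec_cr(rec, rule_dec[[rn]], h_eval)
      mc <- matched_comparison(rocs[[nm]], ss[["sensitivity"]],
                               ss[["specificity"]])
      match_rows[[length(match_rows) + 1]] <- data.frame(
        model = nm, rule = rn,
        rule_sensitivity = ss[["sensitivity"]],
        rule_specificity = ss[["specificity"]],
        model_sens_at_rule_spec = mc$sens_at_matched_spec,
        model_spec_at_rule_sens = mc$spec_at_matched_sens,
        threshold_at_rule_spec = mc$threshold_at_matched_spec,
        threshold_at_rule_sens = mc$threshold_at_matched_sens)
    }
  }
  write_report_csv(do.call(rbind, match_rows), out("report_matched.csv"), hash)

  # sensitivity-analysis subsets
  for (mode in config$sensitivity_modes) {
    if (mode == "period") {
      for (p in unique(rec$calendar_period)) {
        sub <- subset_for_sensitivity(rec, "period", period = p)
        if (sum(sub$event == "krt") == 0) next
        op <- compare_models_report(
          sub, lapply(models, function(m) score_cohort(sub, m, h_eval)),
          lapply(config$rules, evaluate_rule, records = sub),
          cutoffs = config$cutoffs, horizon_years = h_eval,
          max_thresholds = config$max_thresholds)
        write_report_csv(op, out(sprintf("report_operating_%s.csv", p)), hash)
      }
    } else {
      sub <- subset_for_sensitivity(rec, mode, seed = config$seed + 1L)
      if (sum(sub$event == "krt") == 0) next
      op <- compare_models_report(
        sub, lapply(models, function(m) score_cohort(sub, m, h_eval)),
        lapply(config$rules, evaluate_rule, records = sub),
        cutoffs = config$cutoffs, horizon_years = h_eval,
        max_thresholds = config$max_thresholds)
      write_report_csv(op, out(sprintf("report_operating_%s.csv", mode)), hash)
    }
  }

  manifest <- list(
    package = "nephroref",
    version = as.character(utils::packageVersion("nephroref")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, hash = hash,
    horizons = config$horizons, cutoffs = config$cutoffs,
    models = names(models), rules = names(config$rules),
    n_persons_input = nrow(tables$persons),
    n_candidate_records = nrow(cand),
    exclusions = as.list(exq$exclusions),
    n_records = nrow(rec),
    n_krt = sum(rec$event == "krt"),
    n_death = sum(rec$event == "death"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  summary_lines <- c(
    sprintf("nephroref run %s (seed %d)", hash, config$seed),
    sprintf("records: %d from %d persons; KRT %d (%.2f%%), death %d (%.2f%%)",
            nrow(rec), length(unique(rec$person_id)),
            manifest$n_krt, 100 * manifest$n_krt / nrow(rec),
            manifest$n_death, 100 * manifest$n_death / nrow(rec)),
    sprintf("evaluation horizon: %g years", h_eval),
    vapply(names(youden), function(nm) {
      sprintf("%s: C=%.3f Brier=%.4f AUC=%.3f Youden threshold=%.3f (J=%.3f)",
              nm, discrimination$c_index[discrimination$model == nm],
              discrimination$brier[discrimination$model == nm],
              discrimination$auc[discrimination$model == nm],
              youden[[nm]]$threshold, youden[[nm]]$J)
    }, character(1)))
  writeLines(summary_lines, out("summary.txt"))

  invisible(list(records = rec, models = models, risks = scored,
                 rules = rule_dec, rocs = rocs, youden = youden,
                 operating = operating, discrimination = discrimination,
                 dca = dca, manifest = manifest, out_dir = config$out_dir))
}
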