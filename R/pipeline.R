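# End-to-end orchestration: simulate (or load) -> score -> prepare -> fit ->
# evaluate -> pool, with reproducible outputs and a machine-readable
# manifest. This is the package's run-everything entry point; each stage is
# also available as an exported function.

.all_scores <- c("mds", "rmed", "msdps", "hnfi", "dash", "who_hdi", "dqi_i",
                 "hei2010", "hli_diet", "hli_total", "wcrf")

#' Configuration of a full analysis run
#'
#' @param cohort A cohort data frame, or `NULL` to simulate one.
#' @param cohort_config A [cohort_config()] used when `cohort` is `NULL`.
#' @param scores Score columns to analyse (subset of the ten indices).
#' @param outcomes Outcomes to analyse.
#' @param models Model numbers (1 and/or 2).
#' @param meta Run country-level random-effects pooling.
#' @param subgroups Subgroup analyses to run (`"sex"`, `"age"`).
#' @param horizon Follow-up truncation horizon (years).
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param seed Seed for the simulation stage.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = NULL, cohort_config = NULL,
                       scores = .all_scores, outcomes = "all_cause",
                       models = c(1, 2), meta = FALSE, subgroups = character(0),
                       horizon = 10, out_dir = NULL, seed = 1L) {
  bad <- setdiff(scores, .all_scores)
  if (length(bad)) stop("unsupported score(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(outcomes, c("all_cause", "cvd", "cancer", "obesity_cancer"))
  if (length(bad)) stop("unsupported outcome(s): ", paste(bad, collapse = ", "))
  structure(list(cohort = cohort, cohort_config = cohort_config,
                 scores = scores, outcomes = outcomes, models = models,
                 meta = meta, subgroups = subgroups, horizon = horizon,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or takes) a cohort, applies exclusions, computes the requested
#' scores, and for every outcome and model produces: per-SD and quartile
#' hazard-ratio tables with trend tests, C-statistics with deltas against
#' the age-only baseline model, a decile calibration table for Model 2, and
#' (optionally) country-specific fits pooled by random-effects
#' meta-analysis. Deterministic given the seed; every output carries the
#' run's configuration hash.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of result tables (also written as CSV/JSON
#'   under `config$out_dir` when set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- config$cohort
  if (is.null(cohort)) {
    cc <- config$cohort_config %||% cohort_config(seed = config$seed)
    cc$seed <- config$seed
    cohort <- generate_cohort(cc)
  }
  n_in <- nrow(cohort)
  cohort <- apply_exclusions(cohort)
  scores <- score_all(cohort)
  hr_rows <- list(); c_rows <- list(); meta_rows <- list()
  calibration <- list()
  for (outc in config$outcomes) {
    adata <- prepare_analysis_data(cohort, scores, outcome = outc,
                                   score_cols = config$scores,
                                   horizon = config$horizon)
    base_fit <- fit_model(adata, model_spec(outc, score = NULL, model = 1))
    for (sc in config$scores) {
      for (m in config$models) {
        spec <- model_spec(outc, score = sc, model = m)
        fit <- fit_model(adata, spec)
        hr_rows[[length(hr_rows) + 1L]] <- data.frame(
          outcome = outc, score = sc, model = m, term = "per_sd",
          hr = fit$per_sd[["hr"]], lcl = fit$per_sd[["lcl"]],
          ucl = fit$per_sd[["ucl"]], p = fit$per_sd[["p"]])
        qt <- hr_by_quartile_with_trend(adata, spec)
        hr_rows[[length(hr_rows) + 1L]] <- data.frame(
          outcome = outc, score = sc, model = m,
          term = paste0("Q", qt$quartile_hr$quartile),
          hr = qt$quartile_hr$hr, lcl = qt$quartile_hr$lcl,
          ucl = qt$quartile_hr$ucl, p = c(NA, NA, NA, qt$p_trend))
        cmp <- compare_models(base_fit, fit)
        c_rows[[length(c_rows) + 1L]] <- data.frame(
          outcome = outc, score = sc, model = m, c = cmp$c_augmented$c,
          c_baseline = cmp$c_baseline$c, delta_vs_baseline = cmp$delta)
        if (m == 2) {
          pred <- predict_10y_risk(fit, horizon = config$horizon)
          cal <- calibration_table(pred, adata$time, adata$event,
                                   horizon = config$horizon)
          calibration[[paste(outc, sc, sep = "_")]] <- cal
        }
        if (config$meta && m == max(config$models)) {
          est <- fit_by_country(adata, spec)
          pooled <- pool_random_effects(est)
          meta_rows[[length(meta_rows) + 1L]] <- data.frame(
            outcome = outc, score = sc, model = m,
            pooled_hr = exp(pooled$estimate), lcl = exp(pooled$ci[1]),
            ucl = exp(pooled$ci[2]), tau2 = pooled$tau2, I2 = pooled$I2,
            k = pooled$k)
        }
      }
    }
  }
  results <- list(
    hr_table = do.call(rbind, hr_rows),
    cstat_table = do.call(rbind, c_rows),
    calibration = calibration,
    meta_table = if (length(meta_rows)) do.call(rbind, meta_rows) else NULL,
    attrition = c(input = n_in, after_exclusions = nrow(cohort)),
    manifest = list(
      seed = config$seed,
      config_hash = config_hash(config[setdiff(names(config), "cohort")]),
      scores = config$scores, outcomes = config$outcomes,
      models = config$models, horizon = config$horizon,
      n_input = n_in, n_analysed = nrow(cohort),
      package_version = as.character(utils::packageVersion("dietscores")))
  )
  if (length(config$subgroups)) {
    results$subgroups <- subgroup_analyses(cohort, scores, config)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results$hr_table, file.path(config$out_dir, "hr_table.csv"),
              row.names = FALSE)
    write.csv(results$cstat_table, file.path(config$out_dir, "cstat_table.csv"),
              row.names = FALSE)
    cal_tab <- do.call(rbind, lapply(names(results$calibration), function(nm) {
      cbind(model = nm, results$calibration[[nm]]$table,
            overall_ratio = results$calibration[[nm]]$overall_ratio,
            slope = results$calibration[[nm]]$calibration_slope)
    }))
    if (!is.null(cal_tab)) {
      write.csv(cal_tab, file.path(config$out_dir, "calibration.csv"),
                row.names = FALSE)
    }
    if (!is.null(results$meta_table)) {
      write.csv(results$meta_table, file.path(config$out_dir, "meta_table.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(results$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}

#' Sex and age subgroup analyses
#'
#' Refits Model 2 (per-SD) and recomputes the C-statistic within the
#' requested subgroups: sex (men / women) and age at baseline (< 50 /
#' >= 50 years). Subgroups without events are flagged and skipped. Sex
#' subgroup fits are stratified by center only.
#'
#' @param cohort Post-exclusion cohort.
#' @param scores Score table from [score_all()].
#' @param config A [run_config()].
#' @return Data frame: subgroup, level, outcome, score, hr, lcl, ucl, c.
#' @export
subgroup_analyses <- function(cohort, scores, config) {
  defs <- list()
  if ("sex" %in% config$subgroups) {
    defs$sex <- split(seq_len(nrow(cohort)), cohort$sex)
  }
  if ("age" %in% config$subgroups) {
    defs$age <- split(seq_len(nrow(cohort)),
                      ifelse(cohort$age < 50, "under50", "50plus"))
  }
  rows <- list()
  for (sg in names(defs)) {
    for (lev in names(defs[[sg]])) {
      sub <- cohort[defs[[sg]][[lev]], , drop = FALSE]
      strata_vars <- if (sg == "sex") "center" else c("sex", "center")
      for (outc in config$outcomes) {
        adata <- tryCatch(
          prepare_analysis_data(sub, scores, outcome = outc,
                                score_cols = config$scores,
                                horizon = config$horizon),
          error = function(e) NULL)
        if (is.null(adata) || sum(adata$event) == 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            subgroup = sg, level = lev, outcome = outc,
            score = NA_character_, hr = NA_real_, lcl = NA_real_,
            ucl = NA_real_, c = NA_real_, flagged = "no events")
          next
        }
        for (sc in config$scores) {
          spec <- model_spec(outc, score = sc, model = 2,
                             strata = strata_vars)
          fit <- tryCatch(fit_model(adata, spec), error = function(e) NULL)
          if (is.null(fit)) next
          cs <- harrell_c(adata$time, adata$event,
                          fit$fit$linear.predictors, se = "none")
          rows[[length(rows) + 1L]] <- data.frame(
            subgroup = sg, level = lev, outcome = outc, score = sc,
            hr = fit$per_sd[["hr"]], lcl = fit$per_sd[["lcl"]],
            ucl = fit$per_sd[["ucl"]], c = cs$c, flagged = "")
        }
      }
    }
  }
  do.call(rbind, rows)
}
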