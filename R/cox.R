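# Stratified Cox models: the "Model 1" / "Model 2" specifications, per-SD
# and quartile hazard ratios with trend tests. Partial-likelihood fitting is
# delegated to survival::coxph; this module owns design assembly,
# stratification and result extraction.

.model2_covariates <- c("age", "bmi", "smoking", "pa_cambridge", "education")

#' Specify a mortality model
#'
#' Model 1 adjusts for age only; Model 2 adds BMI (continuous), smoking
#' (3 categories), physical activity (4), and education (4). Scores that
#' already contain lifestyle components use reduced Model 2 covariate sets:
#' the total HLI is adjusted for education only, the WCRF score for education
#' and smoking. All models are stratified by sex and study center. An
#' energy-adjusted variant adds total energy (kcal/day, continuous).
#'
#' @param outcome `"all_cause"`, `"cvd"`, `"cancer"` or `"obesity_cancer"`.
#' @param score Score name (a column of the score table), or `NULL` for the
#'   age-only baseline model.
#' @param exposure `"z"` (per-SD, standardized) or `"quartile"`.
#' @param model 1 or 2.
#' @param energy_adjusted Add `energy_kcal` to the covariates.
#' @param ties Tie handling passed to the Cox fitter (`"efron"` default).
#' @param strata Stratification columns.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome = "all_cause", score = NULL, exposure = "z",
                       model = 1, energy_adjusted = FALSE, ties = "efron",
                       strata = c("sex", "center")) {
  outcome <- match.arg(outcome, c("all_cause", "cvd", "cancer",
                                  "obesity_cancer"))
  exposure <- match.arg(exposure, c("z", "quartile"))
  stopifnot(model %in% c(1, 2))
  covariates <- "age"
  if (model == 2 && !is.null(score)) {
    covariates <- switch(score,
      hli_total = c("age", "education"),
      wcrf = c("age", "education", "smoking"),
      .model2_covariates)
  } else if (model == 2) {
    covariates <- .model2_covariates
  }
  if (energy_adjusted) covariates <- c(covariates, "energy_kcal")
  exposure_col <- if (is.null(score)) NULL else {
    paste0(if (exposure == "z") "z_" else "q_", score)
  }
  if (!is.null(exposure_col) && exposure_col %in% covariates) {
    stop("invalid model specification: exposure '", exposure_col,
         "' also appears as a covariate")
  }
  if (any(strata %in% covariates)) {
    stop("invalid model specification: strata variable(s) ",
         paste(intersect(strata, covariates), collapse = ", "),
         " must not appear as covariates")
  }
  structure(list(outcome = outcome, score = score, exposure = exposure,
                 exposure_col = exposure_col, model = model,
                 covariates = covariates, energy_adjusted = energy_adjusted,
                 ties = ties, strata = strata),
            class = "model_spec")
}

#' Assemble the analysis table for one outcome
#'
#' Merges cohort covariates, standardized/quartiled scores and the truncated
#' outcome records, and drops subjects with missing covariates listwise
#' (counts logged in attribute `listwise_dropped`).
#'
#' @param cohort Cohort data frame (post-exclusion).
#' @param scores Score table from [score_all()], or `NULL` if the cohort
#'   already carries score columns.
#' @param outcome Outcome name.
#' @param score_cols Score columns to standardize and quartile.
#' @param horizon Truncation horizon (years).
#' @return Analysis data frame with `time`, `event`, `z_*`, `q_*` columns.
#' @export
prepare_analysis_data <- function(cohort, scores = NULL,
                                  outcome = "all_cause",
                                  score_cols = NULL, horizon = 10) {
  data <- if (is.null(scores)) cohort else {
    merge(cohort, scores, by = "subject_id", sort = FALSE)
  }
  if (is.null(score_cols)) {
    score_cols <- intersect(c("mds", "rmed", "msdps", "hnfi", "dash",
                              "who_hdi", "dqi_i", "hei2010", "hli_diet",
                              "hli_total", "wcrf", "latent_dq"), names(data))
  }
  keep <- complete.cases(data[, intersect(c(.model2_covariates, "sex",
                                            "center"), names(data))])
  dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  data <- standardize_scores(data, score_cols)
  data <- assign_quartiles(data, score_cols)
  rec <- outcome_records(data, outcome, horizon)
  data$time <- rec$time
  data$event <- rec$event
  attr(data, "listwise_dropped") <- dropped
  data
}

.spec_formula <- function(spec, exposure_term = NULL) {
  rhs <- c(exposure_term %||% spec$exposure_col, spec$covariates,
           sprintf("strata(%s)", paste(spec$strata, collapse = ", ")))
  as.formula(paste("survival::Surv(time, event) ~",
                   paste(rhs, collapse = " + ")))
}

#' Fit a stratified Cox model
#'
#' Fits the specified proportional-hazards model with Efron tie handling
#' (Breslow by flag via `spec$ties`), stratified by sex and center, and
#' extracts the per-SD hazard ratio with 95% CI when the exposure is a
#' standardized score.
#'
#' @param data Analysis data from [prepare_analysis_data()].
#' @param spec A [model_spec()].
#' @return Object of class `cox_fit_result`: coefficient table, per-SD HR
#'   and CI, n, events, convergence info, and the underlying `coxph` fit.
#' @export
fit_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  for (v in intersect(c("smoking", "education", "pa_cambridge"),
                      spec$covariates)) {
    data[[v]] <- factor(data[[v]])
  }
  fml <- .spec_formula(spec)
  fit <- survival::coxph(fml, data = data, ties = spec$ties, x = FALSE,
                         model = FALSE)
  if (!is.null(fit$fail)) stop("Cox model failed to converge")
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    loghr = s$coefficients[, "coef"],
                    se = s$coefficients[, "se(coef)"],
                    hr = s$coefficients[, "exp(coef)"],
                    lcl = s$conf.int[, "lower .95"],
                    ucl = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  per_sd <- NULL
  if (!is.null(spec$exposure_col) && spec$exposure == "z") {
    row <- tab[tab$term == spec$exposure_col, ]
    per_sd <- c(hr = row$hr, lcl = row$lcl, ucl = row$ucl,
                loghr = row$loghr, se = row$se, p = row$p)
  }
  structure(list(spec = spec, coefficients = tab, per_sd = per_sd,
                 n = fit$n, events = fit$nevent,
                 converged = is.null(fit$fail),
                 fit = fit, data = data),
            class = "cox_fit_result")
}

#' Quartile hazard ratios with linear trend test
#'
#' Fits the model with the score quartile as a 4-level factor (Q1 reference)
#' and reports Q2-Q4 hazard ratios, then refits with the quartile index
#' entered as a single continuous term and reports its Wald p-value as the
#' trend test. A quartile with zero events is flagged non-estimable.
#'
#' @inheritParams fit_model
#' @return List: `quartile_hr` table (Q1 reference row included), `p_trend`,
#'   `n`, `events`.
#' @export
hr_by_quartile_with_trend <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"), !is.null(spec$score))
  qcol <- paste0("q_", spec$score)
  if (is.null(data[[qcol]])) stop("quartile column ", qcol, " missing")
  spec_q <- spec
  spec_q$exposure <- "quartile"
  spec_q$exposure_col <- qcol
  data$.qf <- factor(data[[qcol]], levels = 1:4)
  events_by_q <- tapply(data$event, data$.qf, sum)
  fitf <- fit_model(transform(data, .qf = .qf), local({
    s <- spec_q; s$exposure_col <- ".qf"; s
  }))
  tab <- fitf$coefficients
  qtab <- data.frame(quartile = 1:4, hr = NA_real_, lcl = NA_real_,
                     ucl = NA_real_, estimable = TRUE)
  qtab[1, c("hr", "lcl", "ucl")] <- c(1, NA, NA)
  for (k in 2:4) {
    row <- tab[tab$term == paste0(".qf", k), ]
    if (nrow(row) == 1 && isTRUE(events_by_q[[k]] > 0)) {
      qtab[k, c("hr", "lcl", "ucl")] <- c(row$hr, row$lcl, row$ucl)
    } else {
      qtab$estimable[k] <- FALSE
    }
  }
  data$.qnum <- as.numeric(data[[qcol]])
  fitn <- fit_model(data, local({
    s <- spec_q; s$exposure_col <- ".qnum"; s
  }))
  trow <- fitn$coefficients[fitn$coefficients$term == ".qnum", ]
  list(quartile_hr = qtab, p_trend = trow$p, trend_loghr = trow$loghr,
       n = fitf$n, events = fitf$events)
}
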