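# Cohort construction: exclusions, outcome records with 10-year truncation,
# within-stratum score standardization and quartile assignment.

#' Exclude subjects with prevalent disease
#'
#' Removes subjects flagged with prevalent cancer, myocardial infarction,
#' angina, stroke or diabetes, logging counts by reason. Idempotent.
#'
#' @param data Cohort data frame with logical `prev_*` columns.
#' @param flags Flag columns to apply.
#' @return Filtered data frame; exclusion counts in attribute
#'   `exclusion_log`.
#' @export
apply_exclusions <- function(data,
                             flags = c("prev_cancer", "prev_mi", "prev_angina",
                                       "prev_stroke", "prev_diabetes")) {
  missing <- setdiff(flags, names(data))
  if (length(missing)) {
    stop("missing exclusion flag column(s): ", paste(missing, collapse = ", "))
  }
  log <- vapply(flags, function(f) sum(data[[f]] %in% TRUE), integer(1))
  any_flag <- Reduce(`|`, lapply(flags, function(f) data[[f]] %in% TRUE))
  out <- data[!any_flag, , drop = FALSE]
  if (!nrow(out)) warning("all subjects excluded; returning an empty cohort")
  attr(out, "exclusion_log") <- c(log, excluded_total = sum(any_flag),
                                  retained = nrow(out))
  out
}

#' Truncate follow-up at a horizon
#'
#' Events after the horizon become censored at the horizon; earlier records
#' are unchanged. Never increases the event count.
#'
#' @param records Data frame with `time` and `event` columns.
#' @param horizon Truncation horizon in years (> 0).
#' @return The records with truncated `time`/`event`.
#' @export
truncate_followup <- function(records, horizon = 10) {
  if (horizon <= 0) stop("horizon must be > 0")
  if (any(records$time <= 0)) stop("follow-up times must be > 0")
  late <- records$time > horizon
  records$event[late] <- 0L
  records$time[late] <- horizon
  records
}

#' Build outcome-specific survival records
#'
#' Maps the generated `time_y`/`event`/`cause` columns to the outcome under
#' analysis. Cause-specific outcomes censor deaths from competing causes at
#' the death time (cause-specific hazard convention); obesity-related cancer
#' uses the `obesity_related` flag. Follow-up is truncated at `horizon`.
#'
#' @param data Cohort data frame.
#' @param outcome One of `"all_cause"`, `"cvd"`, `"cancer"`,
#'   `"obesity_cancer"`.
#' @param horizon Truncation horizon in years.
#' @return Data frame `subject_id`, `time`, `event`, `outcome`.
#' @export
outcome_records <- function(data, outcome = "all_cause", horizon = 10) {
  outcome <- match.arg(outcome, c("all_cause", "cvd", "cancer",
                                  "obesity_cancer"))
  ev <- data$event == 1
  event <- switch(outcome,
    all_cause = ev,
    cvd = ev & data$cause == "cvd",
    cancer = ev & data$cause == "cancer",
    obesity_cancer = ev & data$cause == "cancer" & data$obesity_related %in% TRUE
  )
  rec <- data.frame(subject_id = data$subject_id %||% seq_len(nrow(data)),
                    time = data$time_y, event = as.integer(event),
                    outcome = outcome, stringsAsFactors = FALSE)
  truncate_followup(rec, horizon)
}

#' Standardize scores within sex-by-center strata
#'
#' Adds `z_<score>` columns holding stratum-wise z-scores (sample SD,
#' denominator n-1), so hazard ratios per SD are comparable across scores.
#'
#' @param data Data frame holding the score columns and strata columns.
#' @param cols Score columns to standardize.
#' @param strata Stratification columns (default sex and center).
#' @return `data` with `z_` columns added; per-stratum means/SDs in
#'   attribute `standardization`.
#' @export
standardize_scores <- function(data, cols, strata = c("sex", "center")) {
  stratum <- .stratum_labels(data, strata)
  info <- list()
  for (col in cols) {
    x <- data[[col]]
    if (is.null(x)) stop("score column '", col, "' not found")
    z <- numeric(length(x))
    for (s in levels(stratum)) {
      idx <- which(stratum == s)
      if (length(idx) < 2) {
        stop("stratum '", s, "' has fewer than 2 subjects for score '",
             col, "'")
      }
      m <- mean(x[idx]); sdev <- sd(x[idx])
      if (!is.finite(sdev) || sdev == 0) {
        stop("zero variance in stratum '", s, "' for score '", col, "'")
      }
      z[idx] <- (x[idx] - m) / sdev
      info[[paste(col, s, sep = "/")]] <- c(mean = m, sd = sdev)
    }
    data[[paste0("z_", col)]] <- z
  }
  attr(data, "standardization") <- info
  data
}

#' Assign within-stratum quartiles
#'
#' Adds `q_<score>` columns with quartile labels 1-4 per stratum, boundaries
#' at the 25/50/75% type-7 sample quantiles; a value at a boundary goes to
#' the higher quartile.
#'
#' @inheritParams standardize_scores
#' @return `data` with integer `q_` columns added.
#' @export
assign_quartiles <- function(data, cols, strata = c("sex", "center")) {
  stratum <- .stratum_labels(data, strata)
  if (any(table(stratum) < 4)) {
    stop("stratum too small for quartiles: ",
         paste(names(which(table(stratum) < 4)), collapse = ", "))
  }
  for (col in cols) {
    comps <- list(x = data[[col]])
    names(comps) <- col
    cs <- derive_cutoffs(data, comps, spec = "quartiles", strata = strata)
    data[[paste0("q_", col)]] <- assign_bins(cs, col, data, data[[col]])
  }
  data
}
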