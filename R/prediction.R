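# Predictive-performance machinery: Harrell's C, 10-year risk from the
# stratified Breslow baseline, decile calibration with predicted-to-observed
# ratios, calibration slope, and model comparison by delta C.

#' Harrell's concordance statistic for censored survival
#'
#' C = (concordant + 0.5 x tied-prediction pairs) / usable pairs, where a
#' pair is usable iff its two follow-up times differ and the smaller time
#' carries an event; the pair is concordant when the subject dying earlier
#' has the higher risk score. Ranges from 0.5 (no discrimination; any
#' constant predictor) to 1 (perfect). The standard error is estimated by a
#' grouped (delete-a-group) jackknife over subjects.
#'
#' @param time Follow-up times.
#' @param event Event indicators (0/1).
#' @param risk Risk scores; larger = higher predicted risk.
#' @param se `"jackknife"` or `"none"`.
#' @param groups Number of jackknife groups.
#' @return Object of class `discrimination_result`: `c`, `se`, pair counts.
#' @export
harrell_c <- function(time, event, risk, se = c("jackknife", "none"),
                      groups = 10) {
  se <- match.arg(se)
  stopifnot(length(time) == length(event), length(time) == length(risk))
  if (anyNA(time) || anyNA(event) || anyNA(risk)) {
    stop("missing values in time, event or risk")
  }
  counts <- concordance_pair_counts(as.numeric(time), as.integer(event),
                                    as.numeric(risk))
  if (counts[["usable"]] == 0) stop("no usable pairs for concordance")
  cstat <- (counts[["concordant"]] + 0.5 * counts[["tied"]]) / counts[["usable"]]
  se_val <- NA_real_
  if (se == "jackknife" && length(time) > groups) {
    grp <- rep_len(seq_len(groups), length(time))
    cs <- vapply(seq_len(groups), function(g) {
      keep <- grp != g
      k <- concordance_pair_counts(as.numeric(time[keep]),
                                   as.integer(event[keep]),
                                   as.numeric(risk[keep]))
      if (k[["usable"]] == 0) return(NA_real_)
      (k[["concordant"]] + 0.5 * k[["tied"]]) / k[["usable"]]
    }, numeric(1))
    cs <- cs[is.finite(cs)]
    g <- length(cs)
    if (g >= 2) se_val <- sqrt((g - 1) / g * sum((cs - mean(cs))^2))
  }
  structure(list(c = cstat, se = se_val,
                 concordant = counts[["concordant"]],
                 discordant = counts[["discordant"]],
                 tied = counts[["tied"]], usable = counts[["usable"]],
                 n = length(time)),
            class = "discrimination_result")
}

#' Breslow baseline cumulative hazard per stratum
#'
#' Nonparametric baseline cumulative hazard at `horizon`:
#' H0(t) = sum over event times t_k <= t of d_k / sum(exp(lp_j)) over the
#' stratum's risk set, using the linear predictor on the fit's centered
#' scale.
#'
#' @param time,event Survival data.
#' @param lp Linear predictors (centered as fitted).
#' @param strata Stratum labels (factor/character), or `NULL`.
#' @param horizon Evaluation time.
#' @return Named numeric vector: H0(horizon) per stratum.
#' @export
breslow_cumhaz <- function(time, event, lp, strata = NULL, horizon = 10) {
  if (is.null(strata)) strata <- rep("all", length(time))
  strata <- as.character(strata)
  out <- c()
  for (s in unique(strata)) {
    idx <- strata == s
    ord <- order(time[idx])
    ts <- time[idx][ord]
    ev <- event[idx][ord]
    ex <- exp(lp[idx][ord])
    riskset <- rev(cumsum(rev(ex))) # sum of exp(lp) over subjects with T >= t
    evts <- ts[ev == 1 & ts <= horizon]
    dt <- sort(unique(evts))
    if (!length(dt)) {
      out[s] <- 0
      next
    }
    d <- as.vector(table(factor(evts, levels = dt)))
    denom <- riskset[findInterval(dt, ts, left.open = TRUE) + 1]
    out[s] <- sum(d / denom)
  }
  out
}

#' Predicted 10-year event probability from a stratified Cox fit
#'
#' Computes the per-stratum Breslow baseline cumulative hazard at the
#' horizon on the fit's own data and converts the fitted linear predictors
#' into absolute risks: risk = 1 - exp(-H0_stratum(h) * exp(lp)). Apparent
#' (in-sample) predictions, as used for the calibration assessment.
#'
#' @param fit_result A `cox_fit_result` from [fit_model()].
#' @param horizon Prediction horizon in years.
#' @return Data frame `subject_id`, `lp`, `risk`, `stratum`.
#' @export
predict_10y_risk <- function(fit_result, horizon = 10) {
  stopifnot(inherits(fit_result, "cox_fit_result"))
  data <- fit_result$data
  fit <- fit_result$fit
  lp <- unname(fit$linear.predictors)
  stratum <- as.character(.stratum_labels(data, fit_result$spec$strata))
  h0 <- breslow_cumhaz(data$time, data$event, lp, stratum, horizon)
  missing <- setdiff(unique(stratum), names(h0))
  if (length(missing)) stop("stratum absent from training fit: ",
                            paste(missing, collapse = ", "))
  risk <- 1 - exp(-h0[stratum] * exp(lp))
  data.frame(subject_id = data$subject_id %||% seq_len(nrow(data)),
             lp = lp, risk = unname(risk), stratum = stratum,
             stringsAsFactors = FALSE)
}

#' Decile calibration table and predicted-to-observed ratios
#'
#' Bins subjects by deciles of predicted risk and compares the mean
#' predicted risk with the observed risk per bin (1 - Kaplan-Meier at the
#' horizon by default, to respect censoring; the raw event fraction by
#' flag). Also reports the overall predicted-to-observed ratio and the
#' calibration slope, defined as the coefficient of the linear predictor
#' when refit as the sole covariate in a Cox model on the evaluation data.
#'
#' @param predictions Data frame from [predict_10y_risk()] (needs `risk`
#'   and `lp`).
#' @param time,event Survival data in the same subject order.
#' @param horizon Horizon in years.
#' @param bins Number of predicted-risk bins (10 = deciles).
#' @param observed `"km"` or `"raw"`.
#' @param strata Optional stratum labels for the slope refit.
#' @return Object of class `calibration_result`: per-bin table, overall
#'   ratio, calibration slope.
#' @export
calibration_table <- function(predictions, time, event, horizon = 10,
                              bins = 10, observed = c("km", "raw"),
                              strata = NULL) {
  observed <- match.arg(observed)
  p <- predictions$risk
  if (any(p < 0 | p > 1)) stop("predicted risks must lie in [0, 1]")
  probs <- seq_len(bins - 1) / bins
  bnd <- unique(quantile(p, probs = probs, type = 7, names = FALSE))
  if (length(bnd) < bins - 1) {
    warning("ties in predicted risk collapse some bins; bins were merged")
  }
  bin <- findInterval(p, bnd) + 1L
  levels_present <- sort(unique(bin))
  obs_risk <- function(idx) {
    if (observed == "raw") return(mean(event[idx] == 1 & time[idx] <= horizon))
    km <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
    s <- summary(km, times = horizon, extend = TRUE)$surv
    1 - s
  }
  tab <- do.call(rbind, lapply(seq_along(levels_present), function(i) {
    idx <- which(bin == levels_present[i])
    data.frame(bin = i, n = length(idx), mean_predicted = mean(p[idx]),
               observed = obs_risk(idx))
  }))
  tab$ratio <- tab$mean_predicted / tab$observed
  overall <- mean(p) / obs_risk(seq_along(p))
  slope <- calibration_slope(predictions$lp, time, event, strata)
  structure(list(table = tab, overall_ratio = overall,
                 calibration_slope = slope, horizon = horizon,
                 observed = observed),
            class = "calibration_result")
}

#' Calibration slope of a linear predictor
#'
#' Coefficient of the (fixed) linear predictor when entered as the sole
#' covariate of a Cox model on the evaluation data; 1 means effect sizes
#' neither over- nor under-fitted.
#'
#' @param lp Linear predictor.
#' @param time,event Survival data.
#' @param strata Optional stratum labels.
#' @return Numeric slope.
#' @export
calibration_slope <- function(lp, time, event, strata = NULL) {
  df <- data.frame(time = time, event = event, lp = lp)
  if (is.null(strata)) {
    fit <- survival::coxph(survival::Surv(time, event) ~ lp, data = df)
  } else {
    df$stratum <- strata
    fit <- survival::coxph(survival::Surv(time, event) ~ lp + strata(stratum),
                           data = df)
  }
  unname(coef(fit)[["lp"]])
}

#' Compare two nested risk models by delta C
#'
#' C(augmented) - C(baseline), computed from each fit's linear predictor on
#' the same subjects (hence the same usable-pair set).
#'
#' @param baseline_fit,augmented_fit `cox_fit_result` objects fit on the
#'   same subjects and outcome.
#' @param se Passed to [harrell_c()].
#' @return List: `delta`, `c_baseline`, `c_augmented`.
#' @export
compare_models <- function(baseline_fit, augmented_fit, se = "none") {
  db <- baseline_fit$data; da <- augmented_fit$data
  if (nrow(db) != nrow(da) ||
      !identical(db$subject_id %||% seq_len(nrow(db)),
                 da$subject_id %||% seq_len(nrow(da)))) {
    stop("models were fit on different subjects")
  }
  cb <- harrell_c(db$time, db$event, baseline_fit$fit$linear.predictors,
                  se = se)
  ca <- harrell_c(da$time, da$event, augmented_fit$fit$linear.predictors,
                  se = se)
  list(delta = ca$c - cb$c, c_baseline = cb, c_augmented = ca)
}
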