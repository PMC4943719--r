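# Country-specific fits pooled by DerSimonian-Laird random-effects
# meta-analysis, with Cochran's Q and the I-squared heterogeneity metric.

#' Fit the model separately in each country
#'
#' Runs [fit_model()] within each country and collects the per-SD log
#' hazard ratio and its SE. Countries with no events or a failed fit are
#' flagged and excluded, with a log entry in attribute `excluded`.
#'
#' @param data Analysis data (needs a `country` column and the spec's
#'   exposure/covariates).
#' @param spec A [model_spec()] with a standardized-score exposure.
#' @return Data frame of class `study_estimates`: country, estimate (log
#'   HR), se, n, events.
#' @export
fit_by_country <- function(data, spec) {
  stopifnot(!is.null(data$country))
  rows <- list()
  excluded <- character(0)
  for (cn in sort(unique(data$country))) {
    sub <- data[data$country == cn, , drop = FALSE]
    if (sum(sub$event) == 0) {
      excluded <- c(excluded, paste0(cn, " (no events)"))
      next
    }
    fit <- tryCatch(fit_model(sub, spec), error = function(e) NULL)
    if (is.null(fit) || is.null(fit$per_sd) ||
        !is.finite(fit$per_sd[["se"]]) || fit$per_sd[["se"]] <= 0) {
      excluded <- c(excluded, paste0(cn, " (non-estimable)"))
      next
    }
    rows[[cn]] <- data.frame(country = cn,
                             estimate = fit$per_sd[["loghr"]],
                             se = fit$per_sd[["se"]],
                             n = fit$n, events = fit$events,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no country yielded an estimable fit")
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "excluded") <- excluded
  class(out) <- c("study_estimates", class(out))
  out
}

#' DerSimonian-Laird random-effects pooling
#'
#' Classical moment estimator: with fixed-effect weights w_i = 1/se_i^2,
#' Q = sum w_i (theta_i - theta_fixed)^2,
#' tau^2 = max(0, (Q - (k-1)) / (sum w_i - sum w_i^2 / sum w_i)),
#' I^2 = max(0, (Q - (k-1)) / Q) x 100, and the pooled estimate uses
#' random-effects weights 1/(se_i^2 + tau^2).
#'
#' @param estimates Numeric vector of study estimates (e.g. log HRs or
#'   C-statistics), or a `study_estimates` data frame.
#' @param se Standard errors (ignored when `estimates` is a data frame).
#' @return Object of class `meta_result`: pooled estimate with 95% CI,
#'   tau2, Q, I2 (percent), k, and the random-effects weights.
#' @export
pool_random_effects <- function(estimates, se = NULL) {
  if (is.data.frame(estimates)) {
    se <- estimates$se
    estimates <- estimates$estimate
  }
  k <- length(estimates)
  if (k < 2) stop("random-effects pooling needs at least 2 estimates")
  if (any(!is.finite(se) | se <= 0)) stop("standard errors must be positive")
  w <- 1 / se^2
  fixed <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - fixed)^2)
  df <- k - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(wr * estimates) / sum(wr)
  se_pooled <- sqrt(1 / sum(wr))
  structure(list(estimate = pooled, se = se_pooled,
                 ci = pooled + c(-1, 1) * qnorm(0.975) * se_pooled,
                 tau2 = tau2, Q = Q, I2 = I2, k = k, weights = wr),
            class = "meta_result")
}

#' Pool country C-statistics by random-effects meta-analysis
#'
#' Applies [pool_random_effects()] to per-country discrimination results on
#' the C scale.
#'
#' @param cstats Data frame with columns `c` and `se` (one row per country).
#' @return A `meta_result`.
#' @export
pool_cstatistics <- function(cstats) {
  pool_random_effects(cstats$c, cstats$se)
}
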