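# Harrell's C, Breslow baseline risk, calibration, model comparison.

test_that("Harrell's C matches brute-force enumeration on random cases", {
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    time <- round(runif(n, 1, 10), 1)   # induce some ties
    event <- rbinom(n, 1, 0.6)
    risk <- sample(seq(0.1, 1, 0.1), n, replace = TRUE)
    if (!any(event == 1)) event[1] <- 1
    bf <- brute_force_c(time, event, risk)
    if (bf$usable == 0) next
    got <- harrell_c(time, event, risk, se = "none")
    expect_equal(got$c, bf$c, info = paste("rep", rep))
    expect_equal(got$usable, bf$usable)
  }
})

test_that("worked 5-subject example equals exhaustive pair enumeration", {
  time <- c(2, 4, 6, 8, 10); event <- c(1, 1, 0, 1, 0)
  risk <- c(0.9, 0.7, 0.3, 0.5, 0.1)
  bf <- brute_force_c(time, event, risk)
  got <- harrell_c(time, event, risk, se = "none")
  expect_equal(got$c, bf$c)
  expect_equal(got$c, 1) # risk is the exact reverse ranking of event order
  expect_equal(got$usable, 8)
})

test_that("C has its boundary and invariance properties", {
  set.seed(23)
  time <- rexp(40); event <- rbinom(40, 1, 0.7); risk <- runif(40)
  if (!any(event == 1)) event[1] <- 1
  # constant predictor: all usable pairs tied -> 0.5
  expect_equal(harrell_c(time, event, rep(1, 40), se = "none")$c, 0.5)
  # reversing the predictor maps C to 1 - C
  c1 <- harrell_c(time, event, risk, se = "none")$c
  c2 <- harrell_c(time, event, -risk, se = "none")$c
  expect_equal(c1 + c2, 1)
  # strictly monotone transformation leaves C unchanged
  c3 <- harrell_c(time, event, exp(3 * risk), se = "none")$c
  expect_equal(c1, c3)
  # no usable pairs errors
  expect_error(harrell_c(c(1, 1), c(1, 1), c(0.2, 0.4), se = "none"),
               "usable")
})

test_that("with no censoring at a fixed horizon C equals classical AUC", {
  set.seed(29)
  n <- 60
  risk <- runif(n)
  dead <- rbinom(n, 1, plogis(3 * risk - 1.5))
  # binary-outcome survival encoding: deaths at t=1, survivors censored at t=2
  time <- ifelse(dead == 1, 1, 2)
  got <- harrell_c(time, dead, risk, se = "none")$c
  pos <- risk[dead == 1]; neg <- risk[dead == 0]
  auc <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(got, auc)
})

test_that("C agrees with the survival package on a larger sample", {
  set.seed(31)
  n <- 2000
  risk <- rnorm(n)
  time <- rexp(n, exp(0.8 * risk)); cens <- runif(n, 0, 2)
  event <- as.integer(time <= cens); tobs <- pmin(time, cens)
  got <- harrell_c(tobs, event, risk, se = "none")$c
  ref <- survival::concordance(survival::Surv(tobs, event) ~ risk,
                               reverse = TRUE)$concordance
  expect_equal(got, unname(ref), tolerance = 1e-6)
})

test_that("Breslow baseline matches the hand oracle and powers 10-y risk", {
  time <- c(1, 2, 3, 4, 5, 6); event <- c(1, 0, 1, 1, 0, 0)
  lp <- c(0.5, -0.5, 0, 0.2, -0.2, 0.1)
  h0 <- breslow_cumhaz(time, event, lp, strata = NULL, horizon = 10)
  expect_equal(unname(h0["all"]), brute_force_breslow(time, event, lp, 10))
  # two strata are estimated independently
  st <- c("a", "a", "a", "b", "b", "b")
  h2 <- breslow_cumhaz(time, event, lp, strata = st, horizon = 10)
  expect_equal(unname(h2["a"]),
               brute_force_breslow(time[1:3], event[1:3], lp[1:3], 10))
  expect_equal(unname(h2["b"]),
               brute_force_breslow(time[4:6], event[4:6], lp[4:6], 10))
})

test_that("null-model predicted risk equals the nonparametric estimate", {
  coh <- apply_exclusions(small_cohort(n = 8000, seed = 71))
  ad <- prepare_analysis_data(coh, NULL, outcome = "all_cause",
                              score_cols = "latent_dq")
  ad$noise <- rnorm(nrow(ad)) # predictor unrelated to outcome
  ad <- standardize_scores(ad, "noise"); ad <- assign_quartiles(ad, "noise")
  fit <- fit_model(ad, model_spec("all_cause", "noise", model = 1,
                                  strata = "sex"))
  fit$spec$strata <- "sex"
  pred <- predict_10y_risk(fit)
  for (s in c("male", "female")) {
    idx <- ad$sex == s
    np <- 1 - hand_km(ad$time[idx], ad$event[idx], 10)
    expect_lt(abs(mean(pred$risk[idx]) - np), 0.004)
  }
  # with the baseline held fixed, risk is strictly increasing in the linear
  # predictor within each stratum
  for (s in c("male", "female")) {
    idx <- pred$stratum == s
    ord <- order(fit$fit$linear.predictors[idx])
    expect_true(all(diff(pred$risk[idx][ord]) >= 0))
  }
})

test_that("calibration table matches a hand KM computation on a toy", {
  time <- c(seq(1, 10, length.out = 18), 4, 12)
  event <- c(rep(c(1, 0), 9), 1, 0)
  pred <- data.frame(risk = seq(0.05, 1, length.out = 20) / 2,
                     lp = seq(-1, 1, length.out = 20))
  suppressWarnings(
    cal <- calibration_table(pred, time, event, horizon = 10, bins = 2))
  expect_equal(nrow(cal$table), 2)
  lowhalf <- order(pred$risk)[1:10]
  obs_low <- 1 - hand_km(time[lowhalf], event[lowhalf], 10)
  expect_equal(cal$table$observed[1], obs_low, tolerance = 1e-10)
  expect_equal(cal$table$mean_predicted[1], mean(pred$risk[lowhalf]))
  expect_equal(cal$table$ratio, cal$table$mean_predicted / cal$table$observed)
  # doubling predictions doubles the overall predicted-to-observed ratio
  pred2 <- pred; pred2$risk <- pred2$risk * 2
  cal2 <- calibration_table(pred2, time, event, horizon = 10, bins = 2)
  expect_equal(cal2$overall_ratio, 2 * cal$overall_ratio, tolerance = 1e-10)
})

test_that("comparing a model with itself gives delta C of zero", {
  coh <- apply_exclusions(small_cohort(n = 5000, seed = 73))
  ad <- prepare_analysis_data(coh, NULL, outcome = "all_cause",
                              score_cols = "latent_dq")
  base <- fit_model(ad, model_spec("all_cause", NULL, model = 1))
  expect_equal(compare_models(base, base)$delta, 0)
  aug <- fit_model(ad, model_spec("all_cause", "latent_dq", model = 1))
  cmp <- compare_models(base, aug)
  expect_true(is.finite(cmp$delta))
  expect_error(compare_models(base, local({
    f <- aug; f$data <- f$data[-1, ]; f
  })), "different subjects")
})
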