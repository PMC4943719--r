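# The cohort generator: determinism, config validation, intake structure,
# prevalence flags, and the survival model's ground truth.

test_that("the same config and seed reproduce a byte-identical cohort", {
  c1 <- small_cohort(n = 300, seed = 101)
  c2 <- small_cohort(n = 300, seed = 101)
  expect_identical(c1, c2)
  c3 <- small_cohort(n = 300, seed = 102)
  expect_false(identical(c1$time_y, c3$time_y))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(sex_ratio = 1.4), "sex_ratio")
  expect_error(cohort_config(prevalence_rates = c(cancer = 1.2)),
               "prevalence_rates")
  cc <- cohort_config()
  cc$baseline_hazard$cvd$shape <- -1
  expect_error(validate_cohort_config(cc), "shape")
  cc <- cohort_config()
  cc$censor_year_by_center <- rep(-1, 23)
  expect_error(generate_cohort(cc), "censor_year_by_center")
})

test_that("intakes are strictly positive and energy is macro-consistent", {
  coh <- small_cohort(n = 500, seed = 4)
  fgcols <- grep("^foodgroup_", names(coh), value = TRUE)
  expect_true(all(as.matrix(coh[fgcols]) > 0))
  macro <- 9 * coh$nutrient_fat + 4 * (coh$nutrient_protein + coh$nutrient_carb) +
    7 * coh$nutrient_ethanol
  expect_true(all(abs(macro / coh$energy_kcal - 1) < 0.10))
})

test_that("configured fruit-vegetable correlation is recovered", {
  coh <- generate_cohort(local({
    cc <- cohort_config(n_subjects = 50000, seed = 8)
    cc$calib_n_ref <- 20000
    cc
  }))
  # the intake correlation parameter is conditional on sex (locations are
  # sex-specific), and is specified on the log scale
  r <- sapply(split(seq_len(nrow(coh)), coh$sex), function(i) {
    cor(log(coh$foodgroup_fruit_g[i]), log(coh$foodgroup_vegetables_g[i]))
  })
  expect_true(all(abs(r - 0.3) < 0.02))
})

test_that("degenerate intake scale gives identical intakes", {
  cc <- cohort_config(n_subjects = 20, seed = 5,
                      countries = c(north = 1L))
  cc$calib_n_ref <- 5000
  cc$intake_model$sdlog[] <- 1e-12
  cc$intake_model$shares <- lapply(cc$intake_model$shares, function(s) {
    s$sd <- 0; s$q_loading <- 0; s
  })
  cc$intake_model$q_loading[] <- 0
  cc$intake_model$micro_noise_sd <- 0
  coh <- generate_cohort(cc)
  same_sex <- coh[coh$sex == coh$sex[1], ]
  expect_equal(diff(range(same_sex$foodgroup_fruit_g)), 0, tolerance = 1e-6)
  expect_equal(diff(range(same_sex$energy_kcal)), 0, tolerance = 1e-4)
})

test_that("a non-positive-definite correlation request errors", {
  cc <- cohort_config(n_subjects = 50)
  cc$intake_model$corr[] <- -0.9
  diag(cc$intake_model$corr) <- 1
  expect_error(generate_cohort(cc), "positive definite")
})

test_that("prevalence flags follow their configured rates", {
  coh <- small_cohort(n = 20000, seed = 9)
  p <- mean(coh$prev_cancer)
  # binomial 99% interval around the configured 0.0446
  half <- qnorm(0.995) * sqrt(0.0446 * (1 - 0.0446) / 20000)
  expect_true(abs(p - 0.0446) < half)
  d <- data.frame(x = 1:100)
  set.seed(1)
  expect_true(all(!inject_prevalent_disease(d, c(diabetes = 0))$prev_diabetes))
  set.seed(1)
  expect_true(all(inject_prevalent_disease(d, c(diabetes = 1))$prev_diabetes))
  expect_error(inject_prevalent_disease(d, c(diabetes = 1.1)), "rates")
})

test_that("event fractions are monotone in the baseline Weibull scale", {
  base <- cohort_config(n_subjects = 8000, seed = 33,
                        countries = c(north = 2L, south = 2L))
  base$calib_n_ref <- 20000
  coh1 <- generate_cohort(base)
  slower <- base
  slower$baseline_hazard <- lapply(base$baseline_hazard, function(h) h)
  sc <- dietscores:::.calibrate_scales(base)
  for (cs in names(slower$baseline_hazard)) {
    slower$baseline_hazard[[cs]]$scale <- sc[[cs]] * 2 # larger scale = fewer events
  }
  coh2 <- generate_cohort(slower)
  expect_lt(mean(coh2$event), mean(coh1$event))
})

test_that("zero-effect survival times match the Weibull survivor function", {
  cc <- cohort_config(n_subjects = 40000, seed = 12,
                      countries = c(north = 1L),
                      true_loghr_per_sd = c(cvd = 0, cancer = 0, other = 0),
                      country_sd = 0)
  # remove all covariate effects so the marginal law is exactly Weibull
  for (cs in names(cc$baseline_hazard)) {
    cc$baseline_hazard[[cs]]$loghr_age <- 0
    cc$baseline_hazard[[cs]]$loghr_male <- 0
    cc$baseline_hazard[[cs]]$loghr_smoking <- c(former = 0, current = 0)
    cc$baseline_hazard[[cs]]$loghr_bmi <- 0
    cc$baseline_hazard[[cs]]$scale <- c(cvd = 40, cancer = 30, other = 35)[[cs]]
  }
  coh <- generate_cohort(cc)
  km <- survival::survfit(survival::Surv(time_y, event) ~ 1, data = coh)
  shapes <- sapply(cc$baseline_hazard, `[[`, "shape")
  scales <- sapply(cc$baseline_hazard, `[[`, "scale")
  for (t0 in c(3, 6, 9)) {
    s_true <- exp(-sum((t0 / scales)^shapes))
    s_km <- summary(km, times = t0)$surv
    se_km <- summary(km, times = t0)$std.err
    expect_lt(abs(s_km - s_true), 4 * se_km + 1e-4)
  }
})

test_that("exported cohort columns follow the documented contract", {
  coh <- small_cohort(n = 50, seed = 2)
  expect_true(all(c("subject_id", "country", "center", "sex", "age", "bmi",
                    "smoking", "education", "pa_cambridge", "breastfed",
                    "latent_dq", "energy_kcal", "time_y", "event", "cause",
                    "obesity_related") %in% names(coh)))
  expect_true(all(coh$time_y > 0))
  expect_true(all(coh$cause[coh$event == 0] == "none"))
  expect_true(all(coh$age >= 25 & coh$age <= 70))
  expect_true(all(coh$bmi > 0))
  expect_true(all(paste0("foodgroup_", foodgroup_names(), "_g") %in% names(coh)))
  expect_true(all(paste0("nutrient_", nutrient_names()) %in% names(coh)))
})
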