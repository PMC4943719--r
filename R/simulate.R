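# Synthetic multi-country cohort generator.
#
# Emulates the structure of a large European multi-center nutrition cohort:
# 10 countries / 23 centers, sex-specific covariate and intake distributions,
# correlated log-normal food-group intakes driven in part by a latent
# diet-quality factor, nutrients derived from foods through a fixed
# composition table, and cause-specific Weibull proportional-hazards
# mortality (CVD / cancer / other) with per-center administrative censoring.
# The latent factor is stored so downstream estimates can be checked against
# known ground truth.

.default_countries <- c(denmark = 2L, france = 1L, germany = 2L, greece = 1L,
                        italy = 5L, netherlands = 2L, norway = 1L, spain = 5L,
                        sweden = 2L, uk = 2L)

.intake_groups <- c("fruit", "vegetables", "legumes", "nuts", "cereals",
                    "fish", "meat", "dairy", "eggs", "potatoes", "sweets",
                    "sugary_drinks", "olive_oil", "margarine", "olives",
                    "wine")

.default_intake_model <- function() {
  base_median <- c(fruit = 220, vegetables = 220, legumes = 30, nuts = 10,
                   cereals = 220, fish = 40, meat = 120, dairy = 300,
                   eggs = 25, potatoes = 120, sweets = 80,
                   sugary_drinks = 150, olive_oil = 15, margarine = 10,
                   olives = 5, wine = 120)
  sdlog <- c(fruit = 0.30, vegetables = 0.30, legumes = 0.45, nuts = 0.70,
             cereals = 0.40, fish = 0.45, meat = 0.40, dairy = 0.45,
             eggs = 0.50, potatoes = 0.45, sweets = 0.50,
             sugary_drinks = 0.70, olive_oil = 0.80, margarine = 0.70,
             olives = 0.80, wine = 0.80)
  q_loading <- c(fruit = 0.25, vegetables = 0.25, legumes = 0.25,
                 nuts = 0.25, cereals = 0, fish = 0.20, meat = -0.25,
                 dairy = 0, eggs = 0, potatoes = -0.10, sweets = -0.25,
                 sugary_drinks = -0.25, olive_oil = 0.10, margarine = -0.20,
                 olives = 0.10, wine = 0)
  corr <- matrix(0.10, length(.intake_groups), length(.intake_groups),
                 dimnames = list(.intake_groups, .intake_groups))
  diag(corr) <- 1
  corr["fruit", "vegetables"] <- corr["vegetables", "fruit"] <- 0.30
  shares <- list(
    cabbage = list(parent = "vegetables", base = 0.12, sd = 0.5, q_loading = 0),
    root_vegetables = list(parent = "vegetables", base = 0.18, sd = 0.5, q_loading = 0),
    apples_pears = list(parent = "fruit", base = 0.35, sd = 0.5, q_loading = 0),
    fatty_fish = list(parent = "fish", base = 0.35, sd = 0.5, q_loading = 0.2),
    red_processed_meat = list(parent = "meat", base = 0.65, sd = 0.4, q_loading = -0.3),
    poultry = list(parent = "meat", base = 0.25, sd = 0.4, q_loading = 0.1),
    low_fat_dairy = list(parent = "dairy", base = 0.45, sd = 0.5, q_loading = 0.3),
    wholegrain_bread = list(parent = "cereals", base = 0.15, sd = 0.5, q_loading = 0.4),
    wholegrain_cereals = list(parent = "cereals", base = 0.08, sd = 0.5, q_loading = 0.4)
  )
  list(base_median = base_median, sdlog = sdlog, q_loading = q_loading,
       corr = corr, shares = shares, micro_noise_sd = 0.10)
}

.default_hazard <- function() {
  # Weibull shape and covariate log-HRs per cause; scale = NA means
  # "calibrate so the reference population hits target_event_fractions".
  list(
    cvd = list(shape = 4.0, scale = NA, loghr_age = 0.110, loghr_male = 0.90,
               loghr_smoking = c(former = 0.25, current = 0.80),
               loghr_bmi = 0.040),
    cancer = list(shape = 3.0, scale = NA, loghr_age = 0.090,
                  loghr_male = 0.45,
                  loghr_smoking = c(former = 0.20, current = 0.70),
                  loghr_bmi = 0.010),
    other = list(shape = 2.5, scale = NA, loghr_age = 0.095,
                 loghr_male = 0.50,
                 loghr_smoking = c(former = 0.30, current = 0.90),
                 loghr_bmi = 0)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the marginals of a large pan-European nutrition cohort:
#' mean age 50.8 (SD 9.8) truncated to 25-70, 71.1% women, mean energy
#' 2427.9 kcal/day in men and 1935.4 in women, smoking / education /
#' physical-activity category frequencies and sex-specific BMI close to the
#' published cohort table, and baseline Weibull scales calibrated so that
#' 10-year cumulative mortality in the reference population is 3.4%
#' (0.8% CVD, 1.7% cancer, 0.9% other causes).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param countries Named integer vector: centers per country.
#' @param sex_ratio Fraction female, in \[0, 1\].
#' @param age_mean,age_sd,age_range Age distribution (years), truncated.
#' @param energy_mean_by_sex Target mean energy intake (kcal/day) per sex.
#' @param intake_model Log-normal location/scale, latent-factor loadings,
#'   total log-scale correlation matrix and sub-group share model; see
#'   the package vignette.
#' @param covariate_frequencies Category probabilities per sex for smoking,
#'   education and physical activity, plus BMI mean/SD per sex.
#' @param true_loghr_per_sd Log hazard ratio per SD of the latent
#'   diet-quality factor, per cause (`cvd`, `cancer`, `other`).
#' @param baseline_hazard Per-cause Weibull `shape`/`scale` and covariate
#'   log-HRs; `scale = NA` requests automatic calibration to
#'   `target_event_fractions`.
#' @param target_event_fractions 10-year cause-specific cumulative mortality
#'   targets used when calibrating baseline scales.
#' @param censor_year_by_center Administrative censoring horizon (years) per
#'   center; `NULL` cycles 11, 12, 13, 14 across centers.
#' @param country_loghr Per-country log-hazard offsets; `"auto"` spreads a
#'   centered sequence with SD `country_sd`.
#' @param country_sd SD of the automatic country offsets.
#' @param prevalence_rates Baseline disease prevalences used for the
#'   exclusion flags (cancer, MI, angina, stroke, diabetes).
#' @param obesity_related_flag_prob Fraction of cancer deaths flagged as
#'   obesity-related.
#' @param breastfed_prob Probability a woman reports ever breastfeeding.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 10000,
                          countries = .default_countries,
                          sex_ratio = 0.711,
                          age_mean = 50.8, age_sd = 9.8,
                          age_range = c(25, 70),
                          energy_mean_by_sex = c(male = 2427.9, female = 1935.4),
                          intake_model = .default_intake_model(),
                          covariate_frequencies = NULL,
                          true_loghr_per_sd = c(cvd = log(0.85),
                                                cancer = log(0.90),
                                                other = log(0.87)),
                          baseline_hazard = .default_hazard(),
                          target_event_fractions = c(cvd = 0.008,
                                                     cancer = 0.017,
                                                     other = 0.009),
                          censor_year_by_center = NULL,
                          country_loghr = "auto",
                          country_sd = 0.12,
                          prevalence_rates = c(cancer = 0.0446, mi = 0.0134,
                                               angina = 0.0160,
                                               stroke = 0.0080,
                                               diabetes = 0.0265),
                          obesity_related_flag_prob = 0.384,
                          breastfed_prob = 0.7,
                          seed = 1L) {
  if (is.null(covariate_frequencies)) {
    covariate_frequencies <- list(
      smoking = list(male = c(never = 0.339, former = 0.350, current = 0.297),
                     female = c(never = 0.554, former = 0.225, current = 0.197)),
      education = list(
        male = c(primary = 0.335, technical = 0.249, secondary = 0.138,
                 longer = 0.279),
        female = c(primary = 0.287, technical = 0.225, secondary = 0.249,
                   longer = 0.239)),
      # published activity frequencies leave a missing-category remainder;
      # renormalized here so the four observed categories sum to 1
      pa_cambridge = list(
        male = c(inactive = 0.175, moderately_inactive = 0.306,
                 moderately_active = 0.247, active = 0.249) / 0.977,
        female = c(inactive = 0.207, moderately_inactive = 0.317,
                   moderately_active = 0.216, active = 0.141) / 0.881),
      bmi = list(male = c(mean = 26.4, sd = 3.6),
                 female = c(mean = 24.9, sd = 4.3))
    )
  }
  cfg <- structure(list(
    n_subjects = n_subjects, countries = countries, sex_ratio = sex_ratio,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    energy_mean_by_sex = energy_mean_by_sex, intake_model = intake_model,
    covariate_frequencies = covariate_frequencies,
    true_loghr_per_sd = true_loghr_per_sd, baseline_hazard = baseline_hazard,
    target_event_fractions = target_event_fractions,
    censor_year_by_center = censor_year_by_center,
    country_loghr = country_loghr, country_sd = country_sd,
    prevalence_rates = prevalence_rates,
    obesity_related_flag_prob = obesity_related_flag_prob,
    breastfed_prob = breastfed_prob, seed = as.integer(seed),
    bmi_ref = 25.3, horizon = 10
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param config A `cohort_config` to validate.
#' @export
validate_cohort_config <- function(config) {
  fail <- function(field, why) {
    stop("configuration error in field '", field, "': ", why, call. = FALSE)
  }
  if (!is.numeric(config$n_subjects) || config$n_subjects < 1) {
    fail("n_subjects", "must be >= 1")
  }
  if (!length(config$countries) || any(config$countries < 1)) {
    fail("countries", "needs at least one center per country")
  }
  if (config$sex_ratio < 0 || config$sex_ratio > 1) {
    fail("sex_ratio", "must be a probability in [0, 1]")
  }
  if (config$age_sd <= 0) fail("age_sd", "must be positive")
  if (any(config$energy_mean_by_sex <= 0)) {
    fail("energy_mean_by_sex", "energy targets must be positive")
  }
  for (cs in names(config$baseline_hazard)) {
    h <- config$baseline_hazard[[cs]]
    if (h$shape <= 0) fail(paste0("baseline_hazard$", cs, "$shape"),
                           "Weibull shape must be > 0")
    if (!is.na(h$scale) && h$scale <= 0) {
      fail(paste0("baseline_hazard$", cs, "$scale"),
           "Weibull scale must be > 0")
    }
  }
  if (!is.null(config$censor_year_by_center) &&
      any(config$censor_year_by_center <= 0)) {
    fail("censor_year_by_center", "censoring horizons must be > 0")
  }
  if (any(config$prevalence_rates < 0 | config$prevalence_rates > 1)) {
    fail("prevalence_rates", "rates must be probabilities in [0, 1]")
  }
  for (v in c("smoking", "education", "pa_cambridge")) {
    for (s in c("male", "female")) {
      p <- config$covariate_frequencies[[v]][[s]]
      if (any(p < 0) || abs(sum(p) - 1) > 0.05) {
        fail(paste0("covariate_frequencies$", v, "$", s),
             "category probabilities must be non-negative and sum to 1")
      }
    }
  }
  if (config$obesity_related_flag_prob < 0 ||
      config$obesity_related_flag_prob > 1) {
    fail("obesity_related_flag_prob", "must be a probability")
  }
  invisible(config)
}

.center_table <- function(config) {
  countries <- rep(names(config$countries), times = config$countries)
  centers <- unlist(lapply(names(config$countries), function(cn) {
    paste0(cn, "_c", seq_len(config$countries[[cn]]))
  }))
  horizons <- config$censor_year_by_center
  if (is.null(horizons)) {
    horizons <- rep(c(11, 12, 13, 14), length.out = length(centers))
  } else if (length(horizons) != length(centers)) {
    stop("configuration error in field 'censor_year_by_center': need one ",
         "horizon per center (", length(centers), ")")
  }
  data.frame(country = countries, center = centers, horizon = horizons,
             stringsAsFactors = FALSE)
}

.country_offsets <- function(config) {
  k <- length(config$countries)
  if (identical(config$country_loghr, "auto")) {
    x <- seq_len(k)
    off <- if (k < 2) rep(0, k) else (x - mean(x)) / sd(x) * config$country_sd
  } else {
    off <- rep(config$country_loghr, length.out = k)
  }
  setNames(off, names(config$countries))
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

.draw_covariates <- function(config, n, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  ct <- .center_table(config)
  center_idx <- sample.int(nrow(ct), n, replace = TRUE)
  sex <- ifelse(runif(n) < config$sex_ratio, "female", "male")
  age <- .rtruncnorm(n, config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])
  cf <- config$covariate_frequencies
  draw_cat <- function(freqs) {
    out <- character(n)
    for (s in c("male", "female")) {
      idx <- sex == s
      p <- freqs[[s]] / sum(freqs[[s]])
      out[idx] <- sample(names(p), sum(idx), replace = TRUE, prob = p)
    }
    out
  }
  smoking <- draw_cat(cf$smoking)
  education <- draw_cat(cf$education)
  pa <- draw_cat(cf$pa_cambridge)
  bmi <- numeric(n)
  for (s in c("male", "female")) {
    idx <- sex == s
    bmi[idx] <- .rtruncnorm(sum(idx), cf$bmi[[s]][["mean"]],
                            cf$bmi[[s]][["sd"]], 15, 60)
  }
  breastfed <- sex == "female" & runif(n) < config$breastfed_prob
  data.frame(country = ct$country[center_idx], center = ct$center[center_idx],
             horizon = ct$horizon[center_idx], sex = sex, age = age,
             bmi = bmi, smoking = smoking, education = education,
             pa_cambridge = pa, breastfed = breastfed,
             stringsAsFactors = FALSE)
}

#' Generate correlated food-group and nutrient intakes
#'
#' Draws correlated log-normal food-group intakes whose log-scale
#' correlation matrix is the configured total correlation (a latent
#' diet-quality factor contributes `q_loading[i] * q_loading[j]` of it),
#' splits parent groups into sub-groups with logit-normal shares, and
#' derives nutrients from foods through the fixed composition table plus
#' multiplicative noise on micronutrients. Total energy is the exact
#' macronutrient energy (9/4/4/7 kcal per g fat/protein/carbohydrate/
#' ethanol), so energy consistency holds by construction. Uses the current
#' RNG stream; set a seed beforehand for reproducibility.
#'
#' @param config A `cohort_config`.
#' @param subjects Data frame with columns `sex` and `latent_dq`.
#' @param score_config Scoring configuration supplying the composition table.
#' @return Data frame of `foodgroup_*_g`, `nutrient_*` and `energy_kcal`
#'   columns.
#' @export
generate_intake <- function(config, subjects,
                            score_config = default_score_config()) {
  im <- config$intake_model
  n <- nrow(subjects)
  groups <- names(im$base_median)
  if (any(im$base_median <= 0)) {
    stop("configuration error in field 'intake_model$base_median': ",
         "scale parameters must be positive")
  }
  lam <- im$q_loading[groups]
  sdl <- im$sdlog[groups]
  R <- im$corr[groups, groups]
  # residual correlation after removing the shared latent factor
  Rres <- (R - outer(lam, lam)) /
    outer(sqrt(1 - lam^2), sqrt(1 - lam^2))
  diag(Rres) <- 1
  ch <- tryCatch(chol(Rres), error = function(e) {
    stop("configuration error in field 'intake_model$corr': residual ",
         "correlation matrix is not positive definite", call. = FALSE)
  })
  q <- subjects$latent_dq
  eps <- matrix(rnorm(n * length(groups)), n) %*% ch
  z <- sweep(eps, 2, sqrt(1 - lam^2), "*") + outer(q, lam)

  # sex-specific location shift calibrated so the expected macronutrient
  # energy matches the configured sex means
  comp <- score_config$composition
  dens <- score_config$energy_density[groups]
  mu0 <- log(im$base_median)
  mean_e0 <- sum(dens * exp(mu0 + sdl^2 / 2))
  shift <- log(config$energy_mean_by_sex / mean_e0)
  mu <- outer(ifelse(subjects$sex == "male", shift[["male"]],
                     shift[["female"]]), mu0, "+")
  intakes <- exp(sweep(z, 2, sdl, "*") + mu)
  colnames(intakes) <- groups

  out <- data.frame(row.names = seq_len(n))
  for (g in groups) out[[fg_col(g)]] <- intakes[, g]

  # sub-group shares (logit-normal, some loading on the latent factor)
  share <- function(def) {
    plogis(qlogis(def$base) + def$q_loading * q + def$sd * rnorm(n))
  }
  sh <- lapply(im$shares, share)
  # grain shares must leave room for refined grains; meat shares for "other"
  grain_tot <- pmin(sh$wholegrain_bread + sh$wholegrain_cereals, 0.9)
  scl <- grain_tot / pmax(sh$wholegrain_bread + sh$wholegrain_cereals, 1e-9)
  sh$wholegrain_bread <- sh$wholegrain_bread * scl
  sh$wholegrain_cereals <- sh$wholegrain_cereals * scl
  meat_tot <- pmin(sh$red_processed_meat + sh$poultry, 0.95)
  scl <- meat_tot / pmax(sh$red_processed_meat + sh$poultry, 1e-9)
  sh$red_processed_meat <- sh$red_processed_meat * scl
  sh$poultry <- sh$poultry * scl
  veg_tot <- pmin(sh$cabbage + sh$root_vegetables, 0.9)
  scl <- veg_tot / pmax(sh$cabbage + sh$root_vegetables, 1e-9)
  sh$cabbage <- sh$cabbage * scl
  sh$root_vegetables <- sh$root_vegetables * scl

  for (nm in names(sh)) {
    parent <- im$shares[[nm]]$parent
    out[[fg_col(nm)]] <- sh[[nm]] * intakes[, parent]
  }
  out[[fg_col("refined_grains")]] <-
    intakes[, "cereals"] * (1 - sh$wholegrain_bread - sh$wholegrain_cereals)

  # nutrients from the composition table
  nut_of <- function(key) {
    v <- rep(0, n)
    for (g in groups) v <- v + comp[[g]][[key]] * intakes[, g]
    v
  }
  noise <- function(x) x * exp(rnorm(n, 0, im$micro_noise_sd))
  sfa <- nut_of("sfa"); mufa <- nut_of("mufa"); pufa <- nut_of("pufa")
  protein <- nut_of("protein"); carb <- nut_of("carb")
  free_sugars <- nut_of("free_sugars"); ethanol <- nut_of("ethanol")
  fat <- sfa + mufa + pufa
  wg <- out[[fg_col("wholegrain_bread")]] + out[[fg_col("wholegrain_cereals")]]
  fibre <- noise(nut_of("fibre"))
  out[[nut_col("sfa")]] <- sfa
  out[[nut_col("mufa")]] <- mufa
  out[[nut_col("pufa")]] <- pufa
  out[[nut_col("fat")]] <- fat
  out[[nut_col("protein")]] <- protein
  out[[nut_col("carb")]] <- carb
  out[[nut_col("free_sugars")]] <- free_sugars
  out[[nut_col("cholesterol_mg")]] <- noise(nut_of("cholesterol_mg"))
  out[[nut_col("fibre")]] <- fibre
  out[[nut_col("cereal_fibre")]] <-
    noise(0.075 * wg + 0.025 * out[[fg_col("refined_grains")]])
  out[[nut_col("folate_ug")]] <- noise(nut_of("folate_ug"))
  out[[nut_col("iron_mg")]] <- noise(nut_of("iron_mg"))
  out[[nut_col("calcium_mg")]] <- noise(nut_of("calcium_mg"))
  out[[nut_col("vitc_mg")]] <- noise(nut_of("vitc_mg"))
  out[[nut_col("ethanol")]] <- ethanol
  out[[nut_col("glycaemic_load")]] <-
    noise(pmax(0.45 * carb + 0.25 * free_sugars - 0.35 * fibre - 0.04 * wg, 1))
  ef <- score_config$energy_factors
  out[["energy_kcal"]] <- ef$fat * fat + ef$protein * protein +
    ef$carbohydrate * carb + ef$ethanol * ethanol
  out
}

#' Add prevalent-disease flags
#'
#' Draws independent Bernoulli flags for prevalent cancer, myocardial
#' infarction, angina, stroke and diabetes at the given rates; the exclusion
#' stage ([apply_exclusions()]) removes flagged subjects. Uses the current
#' RNG stream.
#'
#' @param data Cohort data frame.
#' @param rates Named rates in \[0, 1\] for `cancer`, `mi`, `angina`,
#'   `stroke`, `diabetes`.
#' @return `data` with logical `prev_*` columns added.
#' @export
inject_prevalent_disease <- function(data, rates) {
  if (any(rates < 0 | rates > 1)) {
    stop("configuration error in field 'prevalence_rates': rates must be in [0, 1]")
  }
  n <- nrow(data)
  for (nm in names(rates)) {
    data[[paste0("prev_", nm)]] <- runif(n) < rates[[nm]]
  }
  data
}

.hazard_eta <- function(config, cov, q) {
  offs <- .country_offsets(config)
  eta <- sapply(names(config$baseline_hazard), function(cs) {
    h <- config$baseline_hazard[[cs]]
    sm <- c(never = 0, h$loghr_smoking)[cov$smoking]
    config$true_loghr_per_sd[[cs]] * q +
      h$loghr_age * (cov$age - config$age_mean) +
      h$loghr_male * (cov$sex == "male") +
      sm +
      h$loghr_bmi * (cov$bmi - config$bmi_ref) +
      offs[cov$country]
  })
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = nrow(cov))
  eta
}

# Solve baseline Weibull scales so the reference population hits the target
# 10-year cause-specific cumulative mortality fractions. Deterministic
# (fixed internal seeds), cached per configuration.
.calibrate_scales <- function(config) {
  n_ref <- config$calib_n_ref %||% 200000
  key <- config_hash(list(config$countries, config$sex_ratio, config$age_mean,
                          config$age_sd, config$age_range,
                          config$covariate_frequencies,
                          config$true_loghr_per_sd, config$baseline_hazard,
                          config$target_event_fractions, config$country_loghr,
                          config$country_sd, config$bmi_ref, config$horizon,
                          n_ref))
  cache <- .dietscores_env$scale_cache %||% list()
  if (!is.null(cache[[key]])) return(cache[[key]])

  causes <- names(config$baseline_hazard)
  shapes <- vapply(causes, function(cs) config$baseline_hazard[[cs]]$shape,
                   numeric(1))
  targets <- config$target_event_fractions[causes]
  horizon <- config$horizon

  cov1 <- .draw_covariates(config, 10000, seed = 20240871)
  q1 <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(20240872); rnorm(nrow(cov1))
  })
  eta1 <- .hazard_eta(config, cov1, q1)

  # stage 1: single-cause closed form, then fixed-point refinement under
  # competing risks on a time grid
  scales <- vapply(seq_along(causes), function(k) {
    f <- function(lb) {
      mean(1 - exp(-(horizon / exp(lb))^shapes[k] * exp(eta1[, k]))) - targets[k]
    }
    exp(stats::uniroot(f, c(log(1), log(1e6)))$root)
  }, numeric(1))
  tg <- seq(0, horizon, length.out = 101)
  tm <- (tg[-1] + tg[-length(tg)]) / 2
  for (it in 1:6) {
    H <- lapply(seq_along(causes), function(k) {
      outer(exp(eta1[, k]), (tg / scales[k])^shapes[k])
    })
    Htot <- Reduce(`+`, H)
    Smid <- exp(-(Htot[, -1] + Htot[, -ncol(Htot)]) / 2)
    cif <- vapply(seq_along(causes), function(k) {
      dH <- H[[k]][, -1] - H[[k]][, -ncol(Htot)]
      mean(rowSums(dH * Smid))
    }, numeric(1))
    scales <- scales * (cif / targets)^(1 / shapes)
  }

  # stage 2: common rescaling so the all-cause fraction is matched precisely
  # on a large reference draw (closed form, no time grid needed)
  cov2 <- .draw_covariates(config, n_ref, seed = 20240873)
  q2 <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(20240874); rnorm(nrow(cov2))
  })
  eta2 <- .hazard_eta(config, cov2, q2)
  p_total <- sum(targets)
  g <- function(lr) {
    Ht <- 0
    for (k in seq_along(causes)) {
      Ht <- Ht + (horizon / (exp(lr) * scales[k]))^shapes[k] * exp(eta2[, k])
    }
    mean(1 - exp(-Ht)) - p_total
  }
  rho <- exp(stats::uniroot(g, c(log(0.2), log(5)))$root)
  scales <- setNames(rho * scales, causes)

  cache[[key]] <- scales
  .dietscores_env$scale_cache <- cache
  scales
}

#' Generate a synthetic multi-country cohort
#'
#' Produces a cohort table following the package column contract:
#' `subject_id`, `country`, `center`, `sex`, `age`, `bmi`, `smoking`,
#' `education`, `pa_cambridge`, `breastfed`, `prev_*` flags,
#' `foodgroup_*_g`, `nutrient_*`, `energy_kcal`, the stored latent
#' diet-quality factor `latent_dq`, and the survival outcome `time_y`,
#' `event`, `cause` (`cvd`/`cancer`/`other`/`none`) and `obesity_related`.
#'
#' Survival uses the latent-failure-time construction: independent
#' cause-specific Weibull times with proportional hazards on the latent
#' factor and covariates; the observed cause is the earliest latent time,
#' censored administratively at the subject's center horizon.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param score_config Scoring configuration supplying the composition table.
#' @return Cohort data frame, one row per subject.
#' @export
generate_cohort <- function(config, score_config = default_score_config()) {
  validate_cohort_config(config)
  n <- as.integer(config$n_subjects)
  set.seed(config$seed)
  bs <- sample.int(2147483646, 5)

  set.seed(bs[1])
  cov <- .draw_covariates(config, n)
  set.seed(bs[2])
  q <- rnorm(n)
  set.seed(bs[3])
  intake <- generate_intake(config, data.frame(sex = cov$sex, latent_dq = q),
                            score_config)
  set.seed(bs[4])
  cov <- inject_prevalent_disease(cov, config$prevalence_rates)

  set.seed(bs[5])
  eta <- .hazard_eta(config, cov, q)
  causes <- names(config$baseline_hazard)
  scales <- vapply(causes, function(cs) config$baseline_hazard[[cs]]$scale,
                   numeric(1))
  if (anyNA(scales)) scales <- .calibrate_scales(config)
  shapes <- vapply(causes, function(cs) config$baseline_hazard[[cs]]$shape,
                   numeric(1))
  lat <- sapply(seq_along(causes), function(k) {
    u <- runif(n)
    scales[k] * (-log(u) / exp(eta[, k]))^(1 / shapes[k])
  })
  tmin <- do.call(pmin, as.data.frame(lat))
  cause_idx <- max.col(-lat, ties.method = "first")
  event <- tmin <= cov$horizon
  time <- pmin(tmin, cov$horizon)
  cause <- ifelse(event, causes[cause_idx], "none")
  obesity <- event & cause == "cancer" &
    runif(n) < config$obesity_related_flag_prob

  out <- data.frame(subject_id = sprintf("s%07d", seq_len(n)),
                    cov[setdiff(names(cov), "horizon")],
                    latent_dq = q, intake,
                    time_y = time, event = as.integer(event), cause = cause,
                    obesity_related = obesity,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "seed") <- config$seed
  attr(out, "config_hash") <- config_hash(config[setdiff(names(config), "seed")])
  out
}
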