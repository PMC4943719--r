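# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (brute force / direct formula) and share no
# code with the package implementation they check.

# Brute-force Harrell's C over all subject pairs: a pair is usable iff the
# two times differ and the smaller time carries an event; concordant when
# the earlier death has the higher risk score.
brute_force_c <- function(time, event, risk) {
  n <- length(time)
  conc <- disc <- tied <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      early <- if (time[i] < time[j]) i else j
      late <- if (time[i] < time[j]) j else i
      if (event[early] != 1) next
      if (risk[early] > risk[late]) conc <- conc + 1
      else if (risk[early] < risk[late]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  usable <- conc + disc + tied
  list(c = (conc + 0.5 * tied) / usable, usable = usable,
       conc = conc, disc = disc, tied = tied)
}

# Direct double-loop Breslow cumulative hazard in a single stratum.
brute_force_breslow <- function(time, event, lp, horizon) {
  h0 <- 0
  for (tk in sort(unique(time[event == 1 & time <= horizon]))) {
    d <- sum(event == 1 & time == tk)
    h0 <- h0 + d / sum(exp(lp[time >= tk]))
  }
  h0
}

# Direct DerSimonian-Laird computation from the printed formulas.
hand_dl <- function(est, se) {
  w <- 1 / se^2
  fixed <- sum(w * est) / sum(w)
  Q <- sum(w * (est - fixed)^2)
  tau2 <- max(0, (Q - (length(est) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  list(Q = Q, tau2 = tau2,
       I2 = if (Q > 0) max(0, (Q - (length(est) - 1)) / Q) * 100 else 0,
       pooled = sum(wr * est) / sum(wr), se = sqrt(1 / sum(wr)))
}

# Kaplan-Meier survival at a horizon, computed directly.
hand_km <- function(time, event, horizon) {
  s <- 1
  for (tk in sort(unique(time[event == 1 & time <= horizon]))) {
    d <- sum(event == 1 & time == tk)
    r <- sum(time >= tk)
    s <- s * (1 - d / r)
  }
  s
}

# Small single-sex cohort whose 7 DASH components put subject i at quintile
# rank i-ish: beneficial components increase with i, harmful decrease.
dash_toy <- function(n = 10, sex = "male") {
  d <- profile_template(n)
  v <- seq_len(n)
  d$foodgroup_fruit_g <- v
  d$foodgroup_vegetables_g <- v
  d$foodgroup_legumes_g <- v / 2
  d$foodgroup_nuts_g <- v / 2
  d$foodgroup_wholegrain_bread_g <- v / 2
  d$foodgroup_wholegrain_cereals_g <- v / 2
  d$foodgroup_low_fat_dairy_g <- v
  d$foodgroup_sugary_drinks_g <- rev(v)
  d$foodgroup_red_processed_meat_g <- rev(v)
  d$sex <- sex
  d
}

# Diet profile meeting every retained DQI-I criterion at its best level.
dqi_best_profile <- function() {
  d <- profile_template(1, energy = 2040)
  d$foodgroup_fruit_g <- 250
  d$foodgroup_vegetables_g <- 300
  d$foodgroup_cereals_g <- 300
  d$foodgroup_dairy_g <- 150
  d$foodgroup_fish_g <- 50
  d$foodgroup_eggs_g <- 25
  d$foodgroup_legumes_g <- 30
  d$foodgroup_red_processed_meat_g <- 25
  d$nutrient_fibre <- 25
  d$nutrient_protein <- 60
  d$nutrient_carb <- 300
  d$nutrient_fat <- 40
  d$nutrient_sfa <- 10
  d$nutrient_mufa <- 17.5
  d$nutrient_pufa <- 12
  d$nutrient_cholesterol_mg <- 150
  d$nutrient_iron_mg <- 14
  d$nutrient_calcium_mg <- 900
  d$nutrient_vitc_mg <- 80
  d
}

# Profile at exactly the recommended servings of all 13 MSDPS components,
# with all energy from pyramid foods.
msdps_perfect_profile <- function(config = default_score_config()) {
  d <- profile_template(1)
  for (nm in names(config$msdps$components)) {
    def <- config$msdps$components[[nm]]
    d[[paste0("foodgroup_", def$foods[1], "_g")]] <-
      def$recommended * def$serving_g
  }
  # make the pyramid-energy fraction exactly 1
  dens <- config$energy_density
  e <- 0
  for (f in config$msdps$pyramid_foods) {
    e <- e + dens[[f]] * d[[paste0("foodgroup_", f, "_g")]]
  }
  d$energy_kcal <- e
  d
}

# Small cohorts for unit tests: fewer centers (so per-center deciles stay
# meaningful at small n) and a lighter calibration reference draw.
small_cohort <- function(n = 400, seed = 42, ...) {
  cc <- cohort_config(n_subjects = n, seed = seed,
                      countries = c(north = 2L, south = 2L), ...)
  cc$calib_n_ref <- 20000
  generate_cohort(cc)
}
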