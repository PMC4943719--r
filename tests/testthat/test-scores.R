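# The ten score algorithms: worked extremes, enumeration oracles on toy
# cohorts, and the modified (sodium-free) range constants.

test_that("MDS extremes and ethanol window behave as specified", {
  d <- profile_template(2)
  hi <- c(400, 1); lo <- c(50, 2) # subject 1 favorable, subject 2 not
  for (f in c("fruit", "vegetables", "legumes", "cereals", "fish")) {
    d[[paste0("foodgroup_", f, "_g")]] <- hi
  }
  for (f in c("meat", "dairy")) d[[paste0("foodgroup_", f, "_g")]] <- c(20, 300)
  d$nutrient_mufa <- c(30, 10); d$nutrient_sfa <- c(10, 20)
  d$nutrient_ethanol <- c(30, 0)
  d$sex <- "male"
  expect_equal(compute_mds(d), c(9L, 0L))
  # same ethanol, female: 30 g/d is outside the 5-25 window
  d$sex <- "female"
  expect_equal(compute_mds(d)[1], 8L)
})

test_that("MDS on a 4-subject toy equals component-wise enumeration", {
  set.seed(5)
  d <- profile_template(4)
  for (f in c("fruit", "vegetables", "legumes", "cereals", "fish",
              "meat", "dairy")) {
    d[[paste0("foodgroup_", f, "_g")]] <- runif(4, 10, 300)
  }
  d$nutrient_mufa <- runif(4, 5, 40); d$nutrient_sfa <- runif(4, 5, 40)
  d$nutrient_ethanol <- runif(4, 0, 60)
  d$sex <- "male"
  got <- compute_mds(d)
  # enumeration oracle: direct medians and rules
  expected <- integer(4)
  med <- function(x) median(x)
  for (i in 1:4) {
    s <- 0
    for (f in c("fruit", "vegetables", "legumes", "cereals", "fish")) {
      x <- d[[paste0("foodgroup_", f, "_g")]]
      s <- s + (x[i] >= med(x))
    }
    for (f in c("meat", "dairy")) {
      x <- d[[paste0("foodgroup_", f, "_g")]]
      s <- s + (x[i] < med(x))
    }
    r <- d$nutrient_mufa / d$nutrient_sfa
    s <- s + (r[i] >= med(r))
    s <- s + (d$nutrient_ethanol[i] >= 10 && d$nutrient_ethanol[i] <= 50)
    expected[i] <- s
  }
  expect_equal(got, expected)
})

test_that("rMED extremes, olive-oil non-consumer rule, tertile oracle", {
  d <- profile_template(3)
  for (f in c("fruit", "vegetables", "legumes", "cereals", "fish")) {
    d[[paste0("foodgroup_", f, "_g")]] <- c(10, 20, 30)
  }
  for (f in c("meat", "dairy")) d[[paste0("foodgroup_", f, "_g")]] <- c(30, 20, 10)
  d$foodgroup_olive_oil_g <- c(0, 5, 20)
  d$nutrient_ethanol <- c(0, 2, 30)
  d$sex <- "male"
  got <- compute_rmed(d)
  expect_equal(got[3], 18L) # top tertiles + olive oil above median + alcohol
  expect_equal(got[1], 0L)  # bottom everything, non-consumer, no alcohol
  # olive-oil non-consumption scores 0 regardless of other components
  d2 <- d; d2$foodgroup_olive_oil_g <- c(0, 0, 0)
  expect_equal(compute_rmed(d2)[3], 16L)
  # tertile points match a sorting oracle on a 9-subject toy
  set.seed(11)
  d9 <- profile_template(9)
  for (f in c("fruit", "vegetables", "legumes", "cereals", "fish",
              "meat", "dairy")) {
    d9[[paste0("foodgroup_", f, "_g")]] <- sample(seq(10, 90, by = 10))
  }
  d9$foodgroup_olive_oil_g <- 0
  d9$nutrient_ethanol <- 0
  d9$sex <- "male"
  got9 <- compute_rmed(d9)
  oracle_tertile <- function(x) findInterval(x, quantile(x, c(1, 2) / 3,
                                                         type = 7))
  exp9 <- rep(0L, 9)
  for (f in c("fruit", "vegetables", "legumes", "cereals", "fish")) {
    exp9 <- exp9 + oracle_tertile(d9[[paste0("foodgroup_", f, "_g")]])
  }
  for (f in c("meat", "dairy")) {
    exp9 <- exp9 + 2L - oracle_tertile(d9[[paste0("foodgroup_", f, "_g")]])
  }
  expect_equal(got9, exp9)
})

test_that("MSDPS component proration, deductions and normalization", {
  cfg <- default_score_config()
  # 60% of the fruit recommendation scores 6 points on that component
  d <- profile_template(1)
  def <- cfg$msdps$components$fruit
  d$foodgroup_fruit_g <- 0.6 * def$recommended * def$serving_g
  b <- compute_msdps(d, breakdown = TRUE)
  expect_equal(b$fruit, 6)
  # over-consumption: 2x the recommendation scores 0, 2.5x scores -5
  d$foodgroup_fruit_g <- 2 * def$recommended * def$serving_g
  expect_equal(compute_msdps(d, breakdown = TRUE)$fruit, 0)
  d$foodgroup_fruit_g <- 2.5 * def$recommended * def$serving_g
  expect_equal(compute_msdps(d, breakdown = TRUE)$fruit, -5)
  # perfect adherence with all energy from pyramid foods totals 100
  expect_equal(compute_msdps(msdps_perfect_profile(cfg)), 100, tolerance = 1e-9)
})

test_that("HNFI extremes and median oracle on a 6-subject toy", {
  comps <- c("fish", "cabbage", "wholegrain_bread", "apples_pears",
             "root_vegetables", "wholegrain_cereals")
  d <- profile_template(2)
  for (f in comps) d[[paste0("foodgroup_", f, "_g")]] <- c(100, 5)
  d$sex <- "male"
  expect_equal(compute_hnfi(d), c(6L, 0L))
  set.seed(3)
  d6 <- profile_template(6)
  for (f in comps) d6[[paste0("foodgroup_", f, "_g")]] <- runif(6, 0, 100)
  d6$sex <- "female"
  exp6 <- rep(0L, 6)
  for (f in comps) {
    x <- d6[[paste0("foodgroup_", f, "_g")]]
    exp6 <- exp6 + (x >= median(x))
  }
  expect_equal(compute_hnfi(d6), exp6)
})

test_that("DASH spans 7..35 on the quintile toy and matches the rank oracle", {
  d <- dash_toy()
  got <- compute_dash(d)
  expect_equal(got[10], 35L)
  expect_equal(got[1], 7L)
  oracle_quintile <- function(x) findInterval(x, quantile(x, (1:4) / 5,
                                                          type = 7)) + 1L
  v <- seq_len(10)
  exp10 <- 5L * oracle_quintile(v) + 2L * (6L - oracle_quintile(rev(v)))
  expect_equal(got, exp10)
})

test_that("WHO HDI counts components inside guideline ranges", {
  d <- profile_template(1, energy = 2000)
  d$nutrient_sfa <- 10; d$nutrient_pufa <- 10; d$nutrient_protein <- 60
  d$nutrient_cholesterol_mg <- 150; d$nutrient_fibre <- 30
  d$foodgroup_fruit_g <- 300; d$foodgroup_vegetables_g <- 300
  d$nutrient_free_sugars <- 20
  expect_equal(compute_who_hdi(d), 7L)
  # SFA at 12%E loses exactly one point
  d2 <- d; d2$nutrient_sfa <- 0.12 * 2000 / 9
  expect_equal(compute_who_hdi(d2), 6L)
  # everything outside scores 0
  d0 <- profile_template(1, energy = 2000)
  d0$nutrient_sfa <- 60; d0$nutrient_pufa <- 0; d0$nutrient_protein <- 20
  d0$nutrient_cholesterol_mg <- 500; d0$nutrient_fibre <- 5
  d0$nutrient_free_sugars <- 100
  expect_equal(compute_who_hdi(d0), 0L)
  d$energy_kcal <- 0
  expect_error(compute_who_hdi(d), "energy")
})

test_that("HEI-2010 proration, extremes and the 90-point modified maximum", {
  d <- profile_template(1, energy = 2000)
  d$foodgroup_fruit_g <- 300; d$foodgroup_apples_pears_g <- 150
  d$foodgroup_vegetables_g <- 300; d$foodgroup_legumes_g <- 60
  d$foodgroup_cabbage_g <- 30
  d$foodgroup_wholegrain_bread_g <- 90
  d$foodgroup_dairy_g <- 650
  d$foodgroup_meat_g <- 100; d$foodgroup_fish_g <- 50
  d$foodgroup_eggs_g <- 20; d$foodgroup_nuts_g <- 10
  d$nutrient_mufa <- 20; d$nutrient_pufa <- 10; d$nutrient_sfa <- 10
  expect_equal(compute_hei2010(d), 90)
  # whole-grain density exactly halfway between standards: half points
  cfg <- default_score_config()
  def <- cfg$hei2010$components$whole_grains
  d2 <- profile_template(1, energy = 2000)
  halfway <- (def$min_std + def$max_std) / 2
  d2$foodgroup_wholegrain_bread_g <- halfway * 28.35 * 2
  b <- compute_hei2010(d2, breakdown = TRUE)
  expect_equal(b$whole_grains, def$points / 2)
  # zero adequacy intake with maximal moderation violations scores 0
  d0 <- profile_template(1, energy = 2000)
  d0$foodgroup_refined_grains_g <- 300
  d0$foodgroup_sweets_g <- 500
  d0$nutrient_sfa <- 50
  expect_equal(compute_hei2010(d0), 0)
})

test_that("DQI-I variety rule and the 94-point modified maximum", {
  d <- dqi_best_profile()
  b <- compute_dqi_i(d, breakdown = TRUE)
  expect_equal(b$variety_overall, 15) # one serving from each major group
  expect_equal(compute_dqi_i(d), 94)
  # toy profile: total equals the hand-summed component table
  d2 <- profile_template(1, energy = 2000)
  d2$foodgroup_fruit_g <- 120      # >= half the 200 g target -> 3
  d2$foodgroup_vegetables_g <- 300 # full -> 5, and 1 major group serving
  d2$nutrient_fibre <- 25          # 5
  d2$nutrient_protein <- 30        # 6%E -> half of 10%E -> 3
  d2$nutrient_fat <- 55            # 24.75%E -> 3
  d2$nutrient_sfa <- 25            # 11.25%E -> 0
  d2$nutrient_cholesterol_mg <- 350 # 3
  d2$nutrient_carb <- 250
  b2 <- compute_dqi_i(d2, breakdown = TRUE)
  # variety: 2 groups (fruit >= 100 g, vegetable >= 80 g) -> 6; no protein src
  expect_equal(b2$variety_overall, 6)
  expect_equal(b2$variety_protein, 0)
  expect_equal(b2$adequacy, 3 + 5 + 5 + 3) # fruit, veg, fibre, protein
  expect_equal(b2$moderation, 3 + 0 + 3 + 6)
  expect_equal(compute_dqi_i(d2), rowSums(b2))
})

test_that("HLI diet deciles, reversals and graded health index", {
  n <- 20
  d <- profile_template(n)
  v <- seq_len(n)
  d$nutrient_cereal_fibre <- v
  d$nutrient_folate_ug <- v
  d$nutrient_pufa <- v; d$nutrient_sfa <- rep(10, n)
  d$foodgroup_fatty_fish_g <- v
  d$foodgroup_fruit_g <- v; d$foodgroup_vegetables_g <- v
  d$foodgroup_margarine_g <- rev(v)
  d$nutrient_glycaemic_load <- rev(v)
  d$nutrient_ethanol <- rep(30, n); d$nutrient_ethanol[n] <- 0
  d$center <- "c1"
  d$smoking <- "current"; d$smoking[n] <- "never"
  d$pa_cambridge <- "inactive"; d$pa_cambridge[n] <- "active"
  d$bmi <- 31; d$bmi[n] <- 21
  out <- compute_hli(d)
  expect_equal(out$hli_diet[n], 63L)
  expect_equal(out$hli_total[n], 20L)
  expect_equal(out$hli_diet[1], 0L)
  expect_equal(out$hli_total[1], 0L)
  # decile assignment matches the rank oracle for a middling subject
  oracle_decile <- function(x, i) findInterval(x[i], quantile(x, 1:9 / 10,
                                                              type = 7))
  expect_equal(out$hli_diet[7],
               as.integer(5 * oracle_decile(v, 7) +
                            2 * (9 - oracle_decile(rev(v), 7))))
})

test_that("WCRF meets its sex-specific extremes and half-points", {
  # woman meeting all seven recommendations
  d <- profile_template(1, energy = 2000)
  d$sex <- "female"; d$bmi <- 22; d$pa_cambridge <- "active"
  d$breastfed <- TRUE
  d$foodgroup_fruit_g <- 400; d$foodgroup_vegetables_g <- 400
  d$foodgroup_dairy_g <- 400; d$foodgroup_cereals_g <- 300
  d$foodgroup_potatoes_g <- 200; d$foodgroup_fish_g <- 100
  d$nutrient_fibre <- 30
  expect_equal(compute_wcrf(d), 7)
  # man meeting none
  d0 <- profile_template(1, energy = 3000)
  d0$sex <- "male"; d0$bmi <- 35; d0$pa_cambridge <- "inactive"
  d0$breastfed <- FALSE
  d0$foodgroup_fruit_g <- 50; d0$foodgroup_sugary_drinks_g <- 400
  d0$foodgroup_red_processed_meat_g <- 150; d0$foodgroup_meat_g <- 150
  d0$nutrient_fibre <- 5; d0$nutrient_ethanol <- 40
  expect_equal(compute_wcrf(d0), 0)
  # half-adherence cut-offs give half points (BMI and meat here)
  dh <- d
  dh$bmi <- 27 # overweight band -> 0.5
  dh$foodgroup_red_processed_meat_g <- 90 # between 71 and 100 -> 0.5
  expect_equal(compute_wcrf(dh), 6)
})

test_that("score_all returns one row per subject, in declared ranges", {
  coh <- small_cohort(n = 200, seed = 77)
  sc <- score_all(coh)
  expect_equal(nrow(sc), nrow(coh))
  ranges <- list(mds = c(0, 9), rmed = c(0, 18), hnfi = c(0, 6),
                 who_hdi = c(0, 7), dash = c(7, 35), dqi_i = c(0, 94),
                 hei2010 = c(0, 90), hli_diet = c(0, 63),
                 hli_total = c(0, 20), wcrf = c(0, 7))
  for (nm in names(ranges)) {
    expect_true(all(sc[[nm]] >= ranges[[nm]][1] & sc[[nm]] <= ranges[[nm]][2]),
                info = nm)
  }
  expect_true(all(sc$msdps <= 100))
  expect_true(all(sc$wcrf[coh$sex == "male"] <= 6))
  # empty cohort and single subject
  expect_equal(nrow(score_all(coh[0, ])), 0)
  # quantile cut-offs on one subject are degenerate by construction; only
  # the output shape matters here
  one <- suppressWarnings(score_all(coh[3, ]))
  expect_equal(nrow(one), 1)
  expect_true(all(c("mds", "hli_total", "wcrf") %in% names(one)))
})

test_that("subject order does not affect any score", {
  coh <- small_cohort(n = 120, seed = 15)
  sc1 <- score_all(coh)
  perm <- sample(nrow(coh))
  sc2 <- score_all(coh[perm, ])
  sc2 <- sc2[match(sc1$subject_id, sc2$subject_id), ]
  for (nm in setdiff(names(sc1), "subject_id")) {
    expect_equal(unname(sc2[[nm]]), unname(sc1[[nm]]), info = nm)
  }
})

test_that("raising a beneficial intake never lowers quantile scores", {
  coh <- small_cohort(n = 150, seed = 31)
  cs <- score_cutoffs(coh, "dash")
  base <- compute_dash(coh, cs)
  coh2 <- coh
  coh2$foodgroup_fruit_g <- coh2$foodgroup_fruit_g * 1.5
  up <- compute_dash(coh2, cs) # cut-offs held fixed
  expect_true(all(up >= base))
  # and raising a detrimental intake never raises the score
  coh3 <- coh
  coh3$foodgroup_sugary_drinks_g <- coh3$foodgroup_sugary_drinks_g + 100
  down <- compute_dash(coh3, cs)
  expect_true(all(down <= base))
})

test_that("missing intake columns raise a missing-component error", {
  d <- profile_template(2); d$sex <- "male"
  d$foodgroup_fruit_g <- NULL
  expect_error(compute_mds(d), "missing component")
  expect_error(compute_dash(d), "missing component")
})
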