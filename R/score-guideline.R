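# Guideline-based scores with predefined cut-offs: WHO HDI, HEI-2010
# (modified, sodium-free), DQI-I (modified, sodium-free) and MSDPS.

#' WHO Healthy Diet Indicator (0-7)
#'
#' One point per component inside its guideline target range: SFA 0-10%E,
#' PUFA 3-7%E, protein 10-15%E, cholesterol 0-300 mg/d, fibre 25-40 g/d,
#' fruit and vegetables >= 400 g/d, free sugars 0-10%E. Ranges are inclusive
#' and configurable. Energy conversions use 9/4/4/7 kcal per g of
#' fat/protein/carbohydrate/ethanol.
#'
#' @param data Profile data frame (intake columns and `energy_kcal`).
#' @param config Scoring configuration.
#' @return Integer vector of scores in 0..7.
#' @export
compute_who_hdi <- function(data, config = default_score_config()) {
  if (!nrow(data)) return(integer(0))
  e <- energy_kcal(data)
  ef <- config$energy_factors
  t <- config$who_hdi
  pts <- as.integer(in_range(pct_energy(nut(data, "sfa"), ef$fat, e),
                             t$sfa_pct_e[1], t$sfa_pct_e[2])) +
    in_range(pct_energy(nut(data, "pufa"), ef$fat, e),
             t$pufa_pct_e[1], t$pufa_pct_e[2]) +
    in_range(pct_energy(nut(data, "protein"), ef$protein, e),
             t$protein_pct_e[1], t$protein_pct_e[2]) +
    in_range(nut(data, "cholesterol_mg"), t$cholesterol_mg[1], t$cholesterol_mg[2]) +
    in_range(nut(data, "fibre"), t$fibre_g[1], t$fibre_g[2]) +
    in_range(fg_sum(data, c("fruit", "vegetables")),
             t$fruit_veg_g[1], t$fruit_veg_g[2]) +
    in_range(pct_energy(nut(data, "free_sugars"), ef$carbohydrate, e),
             t$free_sugars_pct_e[1], t$free_sugars_pct_e[2])
  as.integer(pts)
}

#' Healthy Eating Index 2010 (modified, 0-90)
#'
#' Density-based scoring per 1000 kcal with linear proration between a
#' minimum and a maximum standard per component; moderation components
#' (refined grains, empty calories) are reverse-scored. The 10-point sodium
#' component is removed, so the default configuration totals 90 points.
#' Component standards, gram-to-cup/ounce conversions and the empty-calorie
#' definition are configuration.
#'
#' @inheritParams compute_who_hdi
#' @param breakdown If `TRUE`, return the per-component score matrix.
#' @return Numeric vector of scores in 0..90 (default configuration), or a
#'   data frame of component scores when `breakdown = TRUE`.
#' @export
compute_hei2010 <- function(data, config = default_score_config(),
                            breakdown = FALSE) {
  if (!nrow(data)) return(numeric(0))
  e <- energy_kcal(data)
  hc <- config$hei2010
  per1000 <- e / 1000
  comp <- list()
  for (nm in names(hc$components)) {
    def <- hc$components[[nm]]
    x <- switch(def$unit,
      ratio = (nut(data, "mufa") + nut(data, "pufa")) /
        pmax(nut(data, "sfa"), 1e-9),
      pct_energy = {
        kcal <- food_energy(data, def$foods, config)
        if (isTRUE(hc$empty_calories_include_ethanol)) {
          kcal <- kcal + config$energy_factors$ethanol * nut(data, "ethanol")
        }
        100 * kcal / e
      },
      # default: servings per 1000 kcal
      fg_sum(data, def$foods) / hc$serving_g[[def$unit]] / per1000
    )
    frac <- (x - def$min_std) / (def$max_std - def$min_std)
    comp[[nm]] <- def$points * pmin(pmax(frac, 0), 1)
  }
  comp <- as.data.frame(comp)
  if (breakdown) comp else rowSums(comp)
}

#' Diet Quality Index - International (modified, 0-94)
#'
#' Four blocks: variety (overall food-group variety 0-15 plus protein-source
#' variety 0-5), adequacy (eight components, 0-5 each), moderation (four
#' retained components, 0-6 each; the sodium row is removed), and overall
#' balance (macronutrient ratio 0-6 plus fatty-acid ratio 0-4). All cut-off
#' tables are configuration; the default maximum is 94 points.
#'
#' @inheritParams compute_hei2010
#' @return Numeric vector of scores in 0..94, or the component data frame.
#' @export
compute_dqi_i <- function(data, config = default_score_config(),
                          breakdown = FALSE) {
  if (!nrow(data)) return(numeric(0))
  e <- energy_kcal(data)
  ef <- config$energy_factors
  dc <- config$dqi_i
  n <- nrow(data)

  # variety: 3 points per major group reaching one serving/day, max 15
  groups_met <- rep(0L, n)
  for (g in dc$variety$major_groups) {
    groups_met <- groups_met + (fg_sum(data, g$foods) / g$serving_g >= 1)
  }
  variety_overall <- 3 * groups_met
  src_met <- rep(0L, n)
  for (g in dc$variety$protein_sources) {
    src_met <- src_met + (fg_sum(data, g$foods) / g$serving_g >= 0.5)
  }
  variety_protein <- c(0, 1, 3, 5)[pmin(src_met, 3L) + 1L]

  adequacy_value <- function(nm) {
    switch(nm,
      vegetables_g = fg(data, "vegetables"),
      fruit_g = fg(data, "fruit"),
      cereals_g = fg(data, "cereals"),
      fibre_g = nut(data, "fibre"),
      protein_pct_e = pct_energy(nut(data, "protein"), ef$protein, e),
      iron_mg = nut(data, "iron_mg"),
      calcium_mg = nut(data, "calcium_mg"),
      vitc_mg = nut(data, "vitc_mg"),
      stop("unknown adequacy component '", nm, "'"))
  }
  adequacy <- rep(0, n)
  for (nm in names(dc$adequacy)) {
    cut <- dc$adequacy[[nm]]
    x <- adequacy_value(nm)
    adequacy <- adequacy + ifelse(x >= cut$full, 5, ifelse(x >= cut$half, 3, 0))
  }

  moderation_value <- function(nm) {
    switch(nm,
      fat_pct_e = pct_energy(nut(data, "fat"), ef$fat, e),
      sfa_pct_e = pct_energy(nut(data, "sfa"), ef$fat, e),
      cholesterol_mg = nut(data, "cholesterol_mg"),
      empty_energy_pct_e = 100 * food_energy(data, dc$empty_energy_foods,
                                             config) / e,
      stop("unknown moderation component '", nm, "'"))
  }
  moderation <- rep(0, n)
  for (nm in names(dc$moderation)) {
    cut <- dc$moderation[[nm]]
    x <- moderation_value(nm)
    moderation <- moderation + ifelse(x <= cut$good, 6, ifelse(x <= cut$mid, 3, 0))
  }

  carb_pe <- pct_energy(nut(data, "carb"), ef$carbohydrate, e)
  prot_pe <- pct_energy(nut(data, "protein"), ef$protein, e)
  fat_pe <- pct_energy(nut(data, "fat"), ef$fat, e)
  macro <- rep(0, n)
  for (w in dc$balance$macro_windows) {
    hit <- macro == 0 &
      in_range(carb_pe, w$carb[1], w$carb[2]) &
      in_range(prot_pe, w$protein[1], w$protein[2]) &
      in_range(fat_pe, w$fat[1], w$fat[2])
    macro[hit] <- w$points
  }
  ps <- nut(data, "pufa") / pmax(nut(data, "sfa"), 1e-9)
  ms <- nut(data, "mufa") / pmax(nut(data, "sfa"), 1e-9)
  fa <- rep(0, n)
  for (w in dc$balance$fatty_acid_windows) {
    hit <- fa == 0 & in_range(ps, w$ps[1], w$ps[2]) & in_range(ms, w$ms[1], w$ms[2])
    fa[hit] <- w$points
  }

  comp <- data.frame(variety_overall = variety_overall,
                     variety_protein = variety_protein,
                     adequacy = adequacy, moderation = moderation,
                     balance_macro = macro, balance_fatty_acid = fa)
  if (breakdown) comp else rowSums(comp)
}

#' Mediterranean Style Dietary Pattern Score (MSDPS, up to 100)
#'
#' Thirteen components scored 10 x (intake / recommended servings) up to the
#' recommendation; over-consumption is deducted linearly in the relative
#' excess (score = 10 - 10 x (ratio - 1)), so a component can be negative.
#' The total is the component sum rescaled to 100 and weighted by the
#' fraction of energy obtained from Mediterranean-pyramid foods.
#'
#' @inheritParams compute_hei2010
#' @return Numeric vector of scores (<= 100, possibly negative), or the
#'   component data frame.
#' @export
compute_msdps <- function(data, config = default_score_config(),
                          breakdown = FALSE) {
  if (!nrow(data)) return(numeric(0))
  mc <- config$msdps
  comp <- list()
  for (nm in names(mc$components)) {
    def <- mc$components[[nm]]
    if (!is.numeric(def$recommended) || def$recommended <= 0) {
      stop("configuration error: msdps component '", nm,
           "' must have a positive recommended serving count")
    }
    ratio <- fg_sum(data, def$foods) / def$serving_g / def$recommended
    comp[[nm]] <- ifelse(ratio <= 1, 10 * ratio, 10 - 10 * (ratio - 1))
  }
  comp <- as.data.frame(comp)
  if (breakdown) return(comp)
  med_frac <- pmin(food_energy(data, mc$pyramid_foods, config) /
                     energy_kcal(data), 1)
  rowSums(comp) / (10 * length(mc$components)) * 100 * med_frac
}
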