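# Scores combining diet with lifestyle: HLI and the WCRF/AICR guideline score.

.hli_diet_components <- function(data, config) {
  list(
    cereal_fibre = nut(data, "cereal_fibre"),
    folate = nut(data, "folate_ug"),
    pufa_sfa_ratio = nut(data, "pufa") / pmax(nut(data, "sfa"), 1e-9),
    fatty_fish = fg(data, "fatty_fish"),
    fruit_veg = fg_sum(data, c("fruit", "vegetables")),
    margarine = fg(data, "margarine"),
    glycaemic_load = nut(data, "glycaemic_load")
  )
}

#' Healthy Lifestyle Index (diet 0-63, total 0-20)
#'
#' The diet half ranks seven components into center-specific deciles scored
#' 0-9 (cereal fibre, folate, PUFA:SFA ratio, fatty fish, fruit and
#' vegetables; margarine and glycaemic load reverse-scored) and sums them to
#' 0-63. The health index awards 0-4 graded points each for smoking status,
#' alcohol, physical activity, BMI and the cohort-wide quintile of the diet
#' score (top quintile 4, bottom 0); the graded mappings are configuration
#' (a binary 0/4 mapping can be encoded the same way).
#'
#' @param data Cohort data frame with intake columns plus `center`,
#'   `smoking`, `pa_cambridge`, `bmi` and `nutrient_ethanol`.
#' @param cutoffs Optional center-specific decile `cutoff_set` from
#'   [score_cutoffs()].
#' @param config Scoring configuration.
#' @return Data frame with columns `hli_diet` (0-63) and `hli_total` (0-20).
#' @export
compute_hli <- function(data, cutoffs = NULL, config = default_score_config()) {
  if (!nrow(data)) {
    return(data.frame(hli_diet = integer(0), hli_total = integer(0)))
  }
  if (is.null(cutoffs)) cutoffs <- score_cutoffs(data, "hli", config)
  hc <- config$hli
  comps <- .hli_diet_components(data, config)
  diet <- rep(0L, nrow(data))
  for (f in hc$diet_direct) {
    diet <- diet + assign_bins(cutoffs, f, data, comps[[f]]) - 1L
  }
  for (f in hc$diet_reversed) {
    diet <- diet + 10L - assign_bins(cutoffs, f, data, comps[[f]])
  }

  for (col in c("smoking", "pa_cambridge", "bmi")) {
    if (is.null(data[[col]])) {
      stop("missing lifestyle field '", col, "' required by HLI")
    }
  }
  smoking_pts <- unlist(hc$smoking_points)[as.character(data$smoking)]
  if (anyNA(smoking_pts)) stop("unknown smoking category in HLI scoring")
  alcohol_pts <- unlist(hc$alcohol_points$points)[
    findInterval(nut(data, "ethanol"), unlist(hc$alcohol_points$bounds)) + 1L]
  activity_pts <- unlist(hc$activity_points)[as.character(data$pa_cambridge)]
  if (anyNA(activity_pts)) stop("unknown physical-activity category in HLI scoring")
  bmi_pts <- unlist(hc$bmi_points$points)[
    findInterval(data$bmi, unlist(hc$bmi_points$bounds)) + 1L]
  quint <- derive_cutoffs(data.frame(diet = diet), list(dietq = diet),
                          spec = "quintiles", strata = NULL)
  diet_pts <- unlist(hc$diet_quintile_points)[
    assign_bins(quint, "dietq", data.frame(diet = diet), diet)]
  data.frame(
    hli_diet = as.integer(diet),
    hli_total = as.integer(smoking_pts + alcohol_pts + activity_pts +
                             bmi_pts + diet_pts)
  )
}

#' WCRF/AICR cancer-prevention guideline score (0-7 women, 0-6 men)
#'
#' Each recommendation is scored 1 (met), 0.5 (half met) or 0 against
#' configured cut-offs: body fatness (BMI), physical activity, foods and
#' drinks promoting weight gain (dietary energy density and sugary drinks,
#' averaged), plant foods (fruit and vegetables and fibre, averaged), animal
#' foods (red and processed meat), alcohol (sex-specific), and breastfeeding
#' (women only).
#'
#' @param data Cohort data frame with intake columns plus `sex`, `bmi`,
#'   `pa_cambridge` and `breastfed`.
#' @param config Scoring configuration.
#' @return Numeric vector; range 0-7 for women, 0-6 for men.
#' @export
compute_wcrf <- function(data, config = default_score_config()) {
  if (!nrow(data)) return(numeric(0))
  wc <- config$wcrf
  for (col in c("sex", "bmi", "pa_cambridge", "breastfed")) {
    if (is.null(data[[col]])) {
      stop("missing lifestyle field '", col, "' required by WCRF scoring")
    }
  }
  grade_max <- function(x, full_max, half_max) {
    ifelse(x <= full_max, 1, ifelse(x <= half_max, 0.5, 0))
  }
  grade_min <- function(x, full_min, half_min) {
    ifelse(x >= full_min, 1, ifelse(x >= half_min, 0.5, 0))
  }

  bf <- wc$body_fatness
  body <- ifelse(in_range(data$bmi, bf$bmi_full[1], bf$bmi_full[2]), 1,
                 ifelse(in_range(data$bmi, bf$bmi_half[1], bf$bmi_half[2]),
                        0.5, 0))
  pa <- ifelse(data$pa_cambridge %in% unlist(wc$physical_activity$full), 1,
               ifelse(data$pa_cambridge %in% unlist(wc$physical_activity$half),
                      0.5, 0))
  food_g <- rep(0, nrow(data))
  for (f in setdiff(names(config$composition),
                    unlist(wc$energy_density$exclude_foods))) {
    food_g <- food_g + fg(data, f)
  }
  ed <- 100 * energy_kcal(data) / pmax(food_g, 1)
  weight_gain <- (grade_max(ed, wc$energy_density$full_max,
                            wc$energy_density$half_max) +
                  grade_max(fg(data, "sugary_drinks"),
                            wc$sugary_drinks_g$full_max,
                            wc$sugary_drinks_g$half_max)) / 2
  plant <- (grade_min(fg_sum(data, c("fruit", "vegetables")),
                      wc$plant_foods$fruit_veg_g$full_min,
                      wc$plant_foods$fruit_veg_g$half_min) +
            grade_min(nut(data, "fibre"),
                      wc$plant_foods$fibre_g$full_min,
                      wc$plant_foods$fibre_g$half_min)) / 2
  animal <- grade_max(fg(data, "red_processed_meat"),
                      wc$animal_foods$red_processed_meat_g$full_max,
                      wc$animal_foods$red_processed_meat_g$half_max)
  eth <- nut(data, "ethanol")
  alcohol <- ifelse(data$sex == "male",
                    grade_max(eth, wc$alcohol$male$full_max,
                              wc$alcohol$male$half_max),
                    grade_max(eth, wc$alcohol$female$full_max,
                              wc$alcohol$female$half_max))
  breast <- ifelse(data$sex == "female",
                   ifelse(data$breastfed %in% TRUE, 1, 0), 0)
  body + pa + weight_gain + plant + animal + alcohol + breast
}

#' Compute all ten diet-quality scores for a cohort
#'
#' Derives all population-dependent cut-offs from the cohort at hand and
#' returns one row per subject with every score. Deterministic; subject
#' order does not affect any score.
#'
#' @param data Cohort data frame following the cohort column contract (see
#'   [generate_cohort()]).
#' @param config Scoring configuration.
#' @return Data frame with `subject_id` (if present) and columns `mds`,
#'   `rmed`, `msdps`, `hnfi`, `dash`, `who_hdi`, `dqi_i`, `hei2010`,
#'   `hli_diet`, `hli_total`, `wcrf`.
#' @export
score_all <- function(data, config = default_score_config()) {
  cols <- c("mds", "rmed", "msdps", "hnfi", "dash", "who_hdi", "dqi_i",
            "hei2010", "hli_diet", "hli_total", "wcrf")
  if (!nrow(data)) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    return(cbind(data.frame(subject_id = character(0)), out))
  }
  hli <- compute_hli(data, config = config)
  out <- data.frame(
    mds = compute_mds(data, config = config),
    rmed = compute_rmed(data, config = config),
    msdps = compute_msdps(data, config = config),
    hnfi = compute_hnfi(data, config = config),
    dash = compute_dash(data, config = config),
    who_hdi = compute_who_hdi(data, config = config),
    dqi_i = compute_dqi_i(data, config = config),
    hei2010 = compute_hei2010(data, config = config),
    hli_diet = hli$hli_diet,
    hli_total = hli$hli_total,
    wcrf = compute_wcrf(data, config = config)
  )
  if (!is.null(data$subject_id)) {
    out <- cbind(data.frame(subject_id = data$subject_id), out)
  }
  out
}

#' Long-format per-component score breakdown
#'
#' @param data Cohort data frame.
#' @param config Scoring configuration.
#' @return Data frame (subject_id, score, component, points) for the scores
#'   with a component breakdown (MSDPS, DQI-I, HEI-2010).
#' @export
score_breakdown <- function(data, config = default_score_config()) {
  ids <- data$subject_id %||% seq_len(nrow(data))
  pieces <- list(
    msdps = compute_msdps(data, config = config, breakdown = TRUE),
    dqi_i = compute_dqi_i(data, config = config, breakdown = TRUE),
    hei2010 = compute_hei2010(data, config = config, breakdown = TRUE)
  )
  do.call(rbind, lapply(names(pieces), function(sc) {
    b <- pieces[[sc]]
    do.call(rbind, lapply(names(b), function(cmp) {
      data.frame(subject_id = ids, score = sc, component = cmp,
                 points = b[[cmp]], row.names = NULL)
    }))
  }))
}
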