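# Quantile-based diet scores: MDS, rMED, HNFI, DASH (modified, sodium-free).
# All use population-dependent, sex-specific cut-offs from derive_cutoffs().

.mds_components <- function(data, config) {
  cmp <- config$mds
  out <- lapply(setNames(c(cmp$beneficial, cmp$detrimental),
                         c(cmp$beneficial, cmp$detrimental)),
                function(f) fg(data, f))
  out$mufa_sfa <- nut(data, "mufa") / pmax(nut(data, "sfa"), 1e-9)
  out
}

#' Sex-specific cut-offs for a quantile-based score
#'
#' Derives the cut-off set a score needs from the cohort at hand: medians for
#' MDS and HNFI, tertiles for rMED, quintiles for DASH (all sex-specific),
#' deciles per center for the HLI diet components.
#'
#' @param data Cohort data frame (needs the score's intake columns and the
#'   stratification columns).
#' @param score One of `"mds"`, `"rmed"`, `"hnfi"`, `"dash"`, `"hli"`.
#' @param config Scoring configuration, see [default_score_config()].
#' @return A `cutoff_set` (for rMED, with the sex-specific olive-oil
#'   consumer median attached as attribute `olive_median`).
#' @export
score_cutoffs <- function(data, score, config = default_score_config()) {
  score <- match.arg(score, c("mds", "rmed", "hnfi", "dash", "hli"))
  switch(score,
    mds = derive_cutoffs(data, .mds_components(data, config),
                         spec = "median", strata = "sex"),
    rmed = {
      cmp <- config$rmed
      comps <- lapply(setNames(c(cmp$beneficial, cmp$detrimental),
                               c(cmp$beneficial, cmp$detrimental)),
                      function(f) fg(data, f))
      cs <- derive_cutoffs(data, comps, spec = "tertiles", strata = "sex")
      oil <- fg(data, "olive_oil")
      med <- vapply(split(oil, data$sex), function(x) {
        cons <- x[x > 0]
        if (length(cons)) median(cons) else NA_real_
      }, numeric(1))
      attr(cs, "olive_median") <- med
      cs
    },
    hnfi = derive_cutoffs(
      data,
      lapply(setNames(config$hnfi$components, config$hnfi$components),
             function(f) fg(data, f)),
      spec = "median", strata = "sex"),
    dash = derive_cutoffs(data, .dash_components(data, config),
                          spec = "quintiles", strata = "sex"),
    hli = derive_cutoffs(data, .hli_diet_components(data, config),
                         spec = "deciles", strata = "center")
  )
}

#' Mediterranean Diet Score (MDS, 0-9)
#'
#' One point per beneficial food group (fruit, vegetables, legumes, grains,
#' fish) at or above the sex-specific median, one point per detrimental group
#' (meat, dairy) below it, one point for a MUFA/SFA ratio at or above its
#' sex-specific median, and one ethanol point inside the moderate window
#' (10-50 g/day men, 5-25 g/day women).
#'
#' @param data Cohort or profile data frame with intake columns and `sex`.
#' @param cutoffs Optional `cutoff_set` from [score_cutoffs()]; derived from
#'   `data` when `NULL`.
#' @param config Scoring configuration.
#' @return Integer vector of scores in 0..9.
#' @export
compute_mds <- function(data, cutoffs = NULL, config = default_score_config()) {
  if (!nrow(data)) return(integer(0))
  if (is.null(cutoffs)) cutoffs <- score_cutoffs(data, "mds", config)
  cmp <- config$mds
  comps <- .mds_components(data, config)
  pts <- rep(0L, nrow(data))
  for (f in cmp$beneficial) {
    pts <- pts + as.integer(assign_bins(cutoffs, f, data, comps[[f]]) == 2L)
  }
  for (f in cmp$detrimental) {
    pts <- pts + as.integer(assign_bins(cutoffs, f, data, comps[[f]]) == 1L)
  }
  pts <- pts + as.integer(assign_bins(cutoffs, "mufa_sfa", data, comps$mufa_sfa) == 2L)
  pts + as.integer(.in_sex_window(nut(data, "ethanol"), data$sex,
                                  cmp$ethanol_window))
}

.in_sex_window <- function(x, sex, window) {
  lo <- ifelse(sex == "male", window$male[1], window$female[1])
  hi <- ifelse(sex == "male", window$male[2], window$female[2])
  x >= lo & x <= hi
}

#' Relative Mediterranean Diet Score (rMED, 0-18)
#'
#' Seven components scored 0/1/2 by sex-specific tertile (fruit, vegetables,
#' legumes, grains, fish; meat and dairy reversed), an olive-oil component
#' (0 for non-consumption, 1 below the sex-specific consumer median, 2 at or
#' above it), and an alcohol component scored 0/2 inside the moderate window.
#'
#' @inheritParams compute_mds
#' @return Integer vector of scores in 0..18.
#' @export
compute_rmed <- function(data, cutoffs = NULL, config = default_score_config()) {
  if (!nrow(data)) return(integer(0))
  if (is.null(cutoffs)) cutoffs <- score_cutoffs(data, "rmed", config)
  cmp <- config$rmed
  pts <- rep(0L, nrow(data))
  for (f in cmp$beneficial) {
    pts <- pts + assign_bins(cutoffs, f, data, fg(data, f)) - 1L
  }
  for (f in cmp$detrimental) {
    pts <- pts + 3L - assign_bins(cutoffs, f, data, fg(data, f))
  }
  oil <- fg(data, "olive_oil")
  med <- attr(cutoffs, "olive_median")[as.character(data$sex)]
  oil_pts <- ifelse(oil <= 0 | is.na(med), 0L, ifelse(oil >= med, 2L, 1L))
  alc <- 2L * .in_sex_window(nut(data, "ethanol"), data$sex, cmp$alcohol_window)
  pts + as.integer(oil_pts) + as.integer(alc)
}

#' Healthy Nordic Food Index (HNFI, 0-6)
#'
#' One point for each of six Nordic foods (fish and shellfish, cabbage,
#' whole-grain bread, apples and pears, root vegetables, whole-grain
#' cereals) at or above the sex-specific median.
#'
#' @inheritParams compute_mds
#' @return Integer vector of scores in 0..6.
#' @export
compute_hnfi <- function(data, cutoffs = NULL, config = default_score_config()) {
  if (!nrow(data)) return(integer(0))
  if (is.null(cutoffs)) cutoffs <- score_cutoffs(data, "hnfi", config)
  pts <- rep(0L, nrow(data))
  for (f in config$hnfi$components) {
    pts <- pts + as.integer(assign_bins(cutoffs, f, data, fg(data, f)) == 2L)
  }
  pts
}

.dash_components <- function(data, config) {
  list(
    fruit = fg(data, "fruit"),
    vegetables = fg(data, "vegetables"),
    legumes_nuts = fg_sum(data, c("legumes", "nuts")),
    wholegrain = fg_sum(data, c("wholegrain_bread", "wholegrain_cereals")),
    low_fat_dairy = fg(data, "low_fat_dairy"),
    sugary_drinks = fg(data, "sugary_drinks"),
    red_processed_meat = fg(data, "red_processed_meat")
  )
}

#' DASH diet score (modified, 7-35)
#'
#' Sodium-free seven-component version: each component is ranked into
#' sex-specific quintiles scored 1-5 (fruit, vegetables, legumes and nuts,
#' whole grains, low-fat dairy) or reverse-scored 5-1 (sweet beverages,
#' red and processed meat), then summed.
#'
#' @inheritParams compute_mds
#' @return Integer vector of scores in 7..35.
#' @export
compute_dash <- function(data, cutoffs = NULL, config = default_score_config()) {
  if (!nrow(data)) return(integer(0))
  if (is.null(cutoffs)) cutoffs <- score_cutoffs(data, "dash", config)
  comps <- .dash_components(data, config)
  pts <- rep(0L, nrow(data))
  for (f in config$dash$beneficial) {
    pts <- pts + assign_bins(cutoffs, f, data, comps[[f]])
  }
  for (f in config$dash$harmful) {
    pts <- pts + 6L - assign_bins(cutoffs, f, data, comps[[f]])
  }
  pts
}
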