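#' Load the default scoring configuration
#'
#' All scoring thresholds, serving sizes, recommended intakes and the
#' food-composition table live in a YAML file shipped with the package
#' (`system.file("extdata", "score_config.yaml", package = "dietscores")`).
#' Every threshold is configuration, not code: load the defaults, modify the
#' returned list, and pass it to the scoring functions via their `config`
#' argument.
#'
#' @param path Optional path to an alternative YAML configuration.
#' @return A nested list with one element per score plus the shared
#'   `composition` table and `energy_factors`.
#' @export
default_score_config <- function(path = NULL) {
  if (is.null(path)) {
    cached <- .dietscores_env$score_config
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "score_config.yaml", package = "dietscores")
  }
  cfg <- yaml::read_yaml(path)
  cfg$energy_density <- .energy_density_table(cfg)
  if (is.null(.dietscores_env$score_config) &&
      basename(path) == "score_config.yaml") {
    .dietscores_env$score_config <- cfg
  }
  cfg
}

# kcal per gram of each food group (parents from the composition table,
# sub-groups inherit from their parent via composition_parent).
.energy_density_table <- function(cfg) {
  ef <- cfg$energy_factors
  dens <- vapply(cfg$composition, function(row) {
    fat <- row$sfa + row$mufa + row$pufa
    ef$fat * fat + ef$protein * row$protein + ef$carbohydrate * row$carb +
      ef$ethanol * row$ethanol
  }, numeric(1))
  for (sub in names(cfg$composition_parent)) {
    dens[[sub]] <- dens[[cfg$composition_parent[[sub]]]]
  }
  dens
}

# Energy (kcal/day) contributed by the listed food groups of a profile table.
food_energy <- function(data, foods, config) {
  dens <- config$energy_density
  out <- rep(0, nrow(data))
  for (f in foods) {
    if (is.na(dens[f])) stop("no energy density configured for food '", f, "'")
    out <- out + dens[[f]] * fg(data, f)
  }
  out
}
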