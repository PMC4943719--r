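# Internal helpers shared across modules.

#' Canonical food-group and nutrient names
#'
#' The cohort column contract: food groups are stored as
#' `foodgroup_<name>_g` (g/day), nutrients as `nutrient_<name>` (g/day unless
#' the name carries `_mg`/`_ug`; `glycaemic_load` is unitless), and total
#' energy as `energy_kcal`.
#'
#' @return Character vector of names.
#' @export
foodgroup_names <- function() {
  c("fruit", "vegetables", "cabbage", "root_vegetables", "legumes", "nuts",
    "cereals", "wholegrain_bread", "wholegrain_cereals", "refined_grains",
    "fish", "fatty_fish", "meat", "red_processed_meat", "poultry", "dairy",
    "low_fat_dairy", "eggs", "potatoes", "sweets", "sugary_drinks",
    "olive_oil", "margarine", "olives", "apples_pears", "wine")
}

#' @rdname foodgroup_names
#' @export
nutrient_names <- function() {
  c("sfa", "mufa", "pufa", "fat", "protein", "carb", "free_sugars",
    "cholesterol_mg", "fibre", "cereal_fibre", "folate_ug", "iron_mg",
    "calcium_mg", "vitc_mg", "ethanol", "glycaemic_load")
}

fg_col <- function(name) paste0("foodgroup_", name, "_g")
nut_col <- function(name) paste0("nutrient_", name)

# Extract a food-group column (g/day); hard error on a missing component.
fg <- function(data, name) {
  col <- fg_col(name)
  if (is.null(data[[col]])) {
    stop("missing component: food group '", name, "' (column ", col,
         ") is required and no imputation policy is set", call. = FALSE)
  }
  data[[col]]
}

nut <- function(data, name) {
  col <- nut_col(name)
  if (is.null(data[[col]])) {
    stop("missing component: nutrient '", name, "' (column ", col,
         ") is required and no imputation policy is set", call. = FALSE)
  }
  data[[col]]
}

# Sum of food-group columns (g/day).
fg_sum <- function(data, names) {
  out <- rep(0, nrow(data))
  for (nm in names) out <- out + fg(data, nm)
  out
}

energy_kcal <- function(data) {
  e <- data[["energy_kcal"]]
  if (is.null(e)) stop("missing column energy_kcal", call. = FALSE)
  if (any(e <= 0)) stop("energy_kcal must be > 0 for all subjects", call. = FALSE)
  e
}

# Percent of energy contributed by `grams` of a macronutrient.
pct_energy <- function(grams, kcal_per_g, energy) 100 * grams * kcal_per_g / energy

in_range <- function(x, lo, hi) x >= lo & x <= hi

#' Empty single-row (or n-row) intake profile
#'
#' Returns a data frame with every food-group and nutrient column set to zero
#' and `energy_kcal` set to `energy`. Convenient for building hand-crafted
#' diet profiles in examples and tests; fill in the components of interest.
#'
#' @param n Number of rows.
#' @param energy Total energy in kcal/day (must be positive).
#' @return A data frame following the intake column contract.
#' @export
profile_template <- function(n = 1, energy = 2000) {
  stopifnot(n >= 1, energy > 0)
  out <- data.frame(row.names = seq_len(n))
  for (f in foodgroup_names()) out[[fg_col(f)]] <- rep(0, n)
  for (u in nutrient_names()) out[[nut_col(u)]] <- rep(0, n)
  out[["energy_kcal"]] <- rep(energy, n)
  out
}

# Stable content hash (polynomial rolling hash over the serialized object),
# used to key caches and stamp run manifests without an external digest
# dependency. Not cryptographic; collisions are irrelevant here.
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
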