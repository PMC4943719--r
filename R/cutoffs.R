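# Population-dependent cut-off machinery.
#
# Every quantile-based index (MDS, rMED, DASH, HNFI, HLI, and the analysis
# quartiles) shares this engine: boundaries are linear-interpolation sample
# quantiles (R type 7) computed within strata, and a value AT a boundary is
# assigned to the higher bin ("at or above counts as above").

.quantile_probs <- list(
  median    = 0.5,
  tertiles  = c(1, 2) / 3,
  quartiles = c(1, 2, 3) / 4,
  quintiles = c(1, 2, 3, 4) / 5,
  deciles   = seq(0.1, 0.9, by = 0.1)
)

#' Derive population-dependent cut-offs within strata
#'
#' Computes, for each component variable, the ordered quantile boundaries
#' (median, tertiles, quartiles, quintiles or deciles) within each stratum of
#' the cohort at hand. Boundaries use the linear-interpolation sample
#' quantile (R's default type 7), fixed so results are reproducible against
#' a sort-based oracle.
#'
#' A stratum in which a component is constant yields degenerate boundaries;
#' a warning is raised and [assign_bins()] places all its subjects in the
#' lowest bin.
#'
#' @param data Cohort data frame.
#' @param components Named list; each element is either a column name in
#'   `data` or a numeric vector of length `nrow(data)` holding the component
#'   variable.
#' @param spec One of `"median"`, `"tertiles"`, `"quartiles"`, `"quintiles"`,
#'   `"deciles"`.
#' @param strata Character vector of stratification columns (e.g. `"sex"`,
#'   `c("sex", "center")`), or `NULL` for a single stratum.
#' @return An object of class `cutoff_set`: boundaries per component per
#'   stratum plus the stratification scheme.
#' @export
derive_cutoffs <- function(data, components, spec = "median", strata = "sex") {
  spec <- match.arg(spec, names(.quantile_probs))
  probs <- .quantile_probs[[spec]]
  stratum <- .stratum_labels(data, strata)
  levs <- levels(stratum)
  if (any(table(stratum) == 0)) {
    stop("empty stratum: ", paste(levs[table(stratum) == 0], collapse = ", "))
  }
  boundaries <- list()
  degenerate <- character(0)
  for (nm in names(components)) {
    x <- .component_vector(data, components[[nm]])
    boundaries[[nm]] <- lapply(setNames(levs, levs), function(s) {
      xs <- x[stratum == s]
      if (!length(xs)) stop("empty stratum '", s, "' for component '", nm, "'")
      b <- unname(quantile(xs, probs = probs, type = 7, names = FALSE))
      if (length(unique(xs)) == 1L) {
        degenerate <<- c(degenerate, paste0(nm, "/", s))
        attr(b, "degenerate") <- TRUE
      }
      b
    })
  }
  if (length(degenerate)) {
    warning("degenerate cut-offs (constant within stratum): ",
            paste(degenerate, collapse = ", "),
            "; subjects in these strata are assigned the lowest bin")
  }
  structure(list(spec = spec, probs = probs, strata = strata,
                 levels = levs, boundaries = boundaries),
            class = "cutoff_set")
}

#' Assign subjects to cut-off bins
#'
#' Maps component values to bins `1..k` using a [derive_cutoffs()] result.
#' A value equal to a boundary goes to the higher bin; degenerate strata
#' (constant component) return the lowest bin for all subjects.
#'
#' @param cutoffs A `cutoff_set`.
#' @param component Component name present in `cutoffs`.
#' @param data Data frame holding the component values and strata columns.
#' @param values Optional numeric vector overriding the component column.
#' @return Integer vector of bin indices.
#' @export
assign_bins <- function(cutoffs, component, data, values = NULL) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  bset <- cutoffs$boundaries[[component]]
  if (is.null(bset)) stop("no cut-offs for component '", component, "'")
  x <- if (is.null(values)) .component_vector(data, component) else values
  stratum <- .stratum_labels(data, cutoffs$strata)
  bins <- integer(length(x))
  for (s in levels(stratum)) {
    idx <- which(stratum == s)
    if (!length(idx)) next
    b <- bset[[s]]
    if (is.null(b)) stop("stratum '", s, "' absent from cut-off set")
    if (isTRUE(attr(b, "degenerate"))) {
      bins[idx] <- 1L
    } else {
      bins[idx] <- findInterval(x[idx], b) + 1L
    }
  }
  bins
}

.stratum_labels <- function(data, strata) {
  if (is.null(strata) || !length(strata)) {
    return(factor(rep("all", nrow(data))))
  }
  missing <- setdiff(strata, names(data))
  if (length(missing)) stop("strata column(s) missing: ",
                            paste(missing, collapse = ", "))
  interaction(data[strata], drop = FALSE, sep = "|", lex.order = TRUE)
}

.component_vector <- function(data, comp) {
  if (is.character(comp) && length(comp) == 1L) {
    if (is.null(data[[comp]])) stop("component column '", comp, "' not found")
    return(data[[comp]])
  }
  if (!is.numeric(comp) || length(comp) != nrow(data)) {
    stop("component must be a column name or a numeric vector of length nrow(data)")
  }
  comp
}
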