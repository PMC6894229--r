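#' Metabolite peak libraries
#'
#' A metabolite library describes, for each metabolite in a panel, the
#' Lorentzian peaks it contributes to a 1D 1H-NMR spectrum together with the
#' population parameters used by the synthetic cohort generator:
#'
#' * `name` -- metabolite identifier (unique per metabolite);
#' * `center_ppm` -- chemical shift of the peak (ppm);
#' * `halfwidth_ppm` -- Lorentzian half-width at half-maximum (ppm);
#' * `rel_area` -- fraction of the metabolite's total area carried by the
#'   peak (sums to 1 within each metabolite);
#' * `base_level` -- mean concentration in the fasting group (arbitrary
#'   units);
#' * `fold_change` -- signed carbohydrate-vs-fasting fold change
#'   (`+r` means the carbohydrate group mean is `r` times the fasting mean,
#'   `-r` means the fasting mean is `r` times the carbohydrate mean);
#' * `cv` -- lognormal between-subject coefficient of variation.
#'
#' Libraries are plain data frames (one row per peak) so they can be stored
#' and exchanged as CSV.
#'
#' @name metabolite-libraries
NULL

# one row per peak; metabolite-level fields repeated across its peaks
.lib_row <- function(name, centers, areas, halfwidth, base_level, fold_change, cv) {
  data.frame(
    name = name,
    center_ppm = centers,
    halfwidth_ppm = halfwidth,
    rel_area = areas,
    base_level = base_level,
    fold_change = fold_change,
    cv = cv,
    stringsAsFactors = FALSE
  )
}

#' Validate a metabolite library
#'
#' Checks the invariants every library must satisfy: positive half-widths and
#' relative areas, per-metabolite relative areas summing to one, positive
#' base levels, absolute fold changes of at least one, and non-negative
#' coefficients of variation.
#'
#' @param library Data frame with columns `name`, `center_ppm`,
#'   `halfwidth_ppm`, `rel_area`, `base_level`, `fold_change`, `cv`.
#' @return The library, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_library <- function(library) {
  required <- c("name", "center_ppm", "halfwidth_ppm", "rel_area",
                "base_level", "fold_change", "cv")
  missing <- setdiff(required, names(library))
  if (length(missing) > 0) {
    stop("library is missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(library$halfwidth_ppm <= 0)) stop("halfwidth_ppm must be > 0")
  if (any(library$rel_area <= 0)) stop("rel_area must be > 0")
  if (any(library$base_level <= 0)) stop("base_level must be > 0")
  if (any(abs(library$fold_change) < 1)) stop("|fold_change| must be >= 1")
  if (any(library$cv < 0)) stop("cv must be >= 0")
  area_sums <- tapply(library$rel_area, library$name, sum)
  if (any(abs(area_sums - 1) > 1e-9)) {
    bad <- names(area_sums)[abs(area_sums - 1) > 1e-9]
    stop("rel_area does not sum to 1 for: ", paste(bad, collapse = ", "))
  }
  per_met <- unique(library[, c("name", "base_level", "fold_change", "cv")])
  if (anyDuplicated(per_met$name)) {
    stop("metabolite-level fields differ across peaks of the same metabolite")
  }
  invisible(library)
}

#' Metabolite names in a library
#' @param library A metabolite library data frame.
#' @return Character vector of unique metabolite names, in order of first
#'   appearance.
#' @export
library_metabolites <- function(library) unique(library$name)

#' Default serum metabolite library
#'
#' A 28-metabolite serum panel covering the 0.1--4.2 ppm CPMG window.
#' Fold changes are the published carbohydrate-vs-fasting serum values for
#' this panel; peak positions and multiplicities are a compact
#' literature-style table (single peaks for most metabolites, doublets for
#' lactate and alanine, the citrate AB pair), chosen so that the default
#' integration windows of the quantification step do not overlap.  The
#' alanine doublet at 1.459/1.470 ppm provides the chemical-shift
#' referencing anchor (left line at 1.47 ppm).
#'
#' The common between-subject coefficient of variation (default 0.06) is
#' the noise level implied by the published t-test p-values at the weakest
#' significant effects (fold changes near 1.06 reaching p of 0.005--0.010
#' at group sizes 26/35 imply a log-scale SD of about 0.06--0.08).
#'
#' @param cv Between-subject lognormal coefficient of variation applied to
#'   every metabolite.
#' @return A metabolite library data frame (one row per peak).
#' @export
build_default_serum_library <- function(cv = 0.06) {
  hw <- 0.002
  rows <- list(
    .lib_row("3-Hydroxybutyrate", 1.20, 1, hw, 1.5, -1.06, cv),
    .lib_row("Acetate",           1.92, 1, hw, 1.0, -1.22, cv),
    .lib_row("Acetoacetate",      2.27, 1, hw, 0.8, -1.25, cv),
    .lib_row("Acetone",           2.22, 1, hw, 0.6, -1.18, cv),
    .lib_row("Alanine",           c(1.470, 1.459), c(0.55, 0.45), hw, 2.0, 1.01, cv),
    .lib_row("Asparagine",        2.95, 1, hw, 0.7, -1.05, cv),
    .lib_row("Citrate",           c(2.54, 2.66), c(0.5, 0.5), hw, 1.2, 1.03, cv),
    .lib_row("Creatine",          3.03, 1, hw, 0.9, -1.01, cv),
    .lib_row("Creatinine",        4.05, 1, hw, 0.9, -1.06, cv),
    .lib_row("Dimethylsulfone",   3.14, 1, hw, 0.4, -1.09, cv),
    .lib_row("Glucose",           3.24, 1, 0.004, 10.0, 1.00, cv),
    .lib_row("Glutamine",         2.44, 1, hw, 1.8, -1.06, cv),
    .lib_row("Glycerol",          3.56, 1, hw, 1.0, -1.05, cv),
    .lib_row("Glycoprotein",      2.04, 1, 0.004, 1.5, -1.06, cv),
    .lib_row("Isoleucine",        0.93, 1, hw, 0.8, -1.26, cv),
    .lib_row("Isopropyl alcohol", 1.17, 1, hw, 0.3, -1.12, cv),
    .lib_row("Lactate",           c(1.326, 1.337), c(0.5, 0.5), hw, 5.0, 1.36, cv),
    .lib_row("Leucine",           0.96, 1, hw, 1.2, -1.20, cv),
    .lib_row("Lysine",            1.72, 1, hw, 1.0, -1.12, cv),
    .lib_row("Methanol",          3.36, 1, hw, 0.3, -1.04, cv),
    .lib_row("Methionine",        2.13, 1, hw, 0.4, -1.11, cv),
    .lib_row("N-acetylated groups", 2.08, 1, 0.004, 1.5, -1.15, cv),
    .lib_row("Phenylalanine",     3.11, 1, hw, 0.6, -1.12, cv),
    .lib_row("Proline",           1.99, 1, hw, 0.6, -1.03, cv),
    .lib_row("Propylene Glycol",  1.14, 1, hw, 0.3, -1.13, cv),
    .lib_row("Pyruvate",          2.37, 1, hw, 0.5, 1.27, cv),
    .lib_row("Threonine",         3.58, 1, hw, 0.8, -1.07, cv),
    .lib_row("Valine",            1.04, 1, hw, 1.0, -1.31, cv)
  )
  lib <- do.call(rbind, rows)
  validate_library(lib)
}

#' Default tumor-tissue metabolite library
#'
#' A 20-metabolite HR-MAS tissue panel covering the 1.4--4.7 ppm window.
#' Fold changes are the published ER-positive carbohydrate-vs-fasting tissue
#' values; the glutathione effect (fold change 1.103) is applied by the
#' tissue cohort generator only to ER-positive samples.  Peak positions
#' avoid the excluded lipid (4.34--4.27, 4.19--4.14, 2.90--2.70, 2.31--2.18,
#' 2.11--1.92, 1.68--1.50 ppm) and ethanol (3.67--3.62 ppm) windows.
#' Creatine at 3.03 ppm is the referencing anchor.
#'
#' @param cv Between-subject lognormal coefficient of variation applied to
#'   every metabolite.
#' @return A metabolite library data frame (one row per peak).
#' @export
build_default_tissue_library <- function(cv = 0.07) {
  hw <- 0.002
  rows <- list(
    .lib_row("Acetate",              1.90, 1, hw, 0.8, -1.095, cv),
    .lib_row("Alanine",              c(1.470, 1.459), c(0.55, 0.45), hw, 1.5, 1.067, cv),
    .lib_row("Ascorbate",            4.51, 1, hw, 0.5, -1.001, cv),
    .lib_row("Aspartate",            2.66, 1, hw, 0.7, 1.088, cv),
    .lib_row("Choline",              3.19, 1, hw, 1.0, 1.027, cv),
    .lib_row("Creatine",             3.03, 1, hw, 2.0, -1.051, cv),
    .lib_row("Glucose",              3.40, 1, 0.004, 3.0, -1.201, cv),
    .lib_row("Glutamate",            2.35, 1, hw, 1.8, 1.055, cv),
    .lib_row("Glutamine",            2.45, 1, hw, 1.2, -1.015, cv),
    .lib_row("Glutathione",          2.95, 1, hw, 1.0, 1.103, cv),
    .lib_row("Glycerophosphocholine", 3.25, 1, hw, 0.9, -1.018, cv),
    .lib_row("Glycine",              3.55, 1, hw, 1.2, 1.090, cv),
    .lib_row("Lactate",              4.11, 1, hw, 2.5, 1.004, cv),
    .lib_row("Leucine",              1.71, 1, hw, 0.6, -1.004, cv),
    .lib_row("Myoinositol",          4.06, 1, hw, 1.5, -1.018, cv),
    .lib_row("Phosphocholine",       3.22, 1, hw, 1.0, 1.051, cv),
    .lib_row("Phosphoethanolamine",  3.98, 1, hw, 0.8, 1.031, cv),
    .lib_row("Scylloinositol",       3.35, 1, hw, 0.4, 1.060, cv),
    .lib_row("Succinate",            2.41, 1, hw, 0.5, 1.067, cv),
    .lib_row("Taurine",              3.43, 1, hw, 1.2, 1.004, cv)
  )
  lib <- do.call(rbind, rows)
  validate_library(lib)
}

#' Tissue exclusion windows
#'
#' The lipid and ethanol chemical-shift windows removed from tissue spectra
#' before normalization and quantification.
#'
#' @return A two-column matrix of `(lo, hi)` ppm bounds, one row per window.
#' @export
tissue_exclusion_windows <- function() {
  m <- rbind(
    c(4.27, 4.34), c(4.14, 4.19), c(2.70, 2.90),
    c(2.18, 2.31), c(1.92, 2.11), c(1.50, 1.68),
    c(3.62, 3.67)
  )
  colnames(m) <- c("lo", "hi")
  m
}
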