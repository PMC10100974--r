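# Genome size -> DNA mass -> cell count conversions, and the heme share of
# cellular iron.

AVOGADRO <- 6.02214076e23

#' DNA mass of a single cell from its genome size
#'
#' One haploid genome copy per cell is assumed; the mass of a base pair is
#' taken as 650 g/mol (double-stranded, sodium-free convention), so
#' `mass = genome_bp * bp_mass / N_A`, expressed in femtograms.
#'
#' @param genome_bp genome size in base pairs (> 0).
#' @param bp_mass average molar mass of one base pair (g/mol); default 650.
#' @return DNA mass per cell in fg.
#' @examples
#' dna_mass_per_cell(6.26e6)  # ~6.76 fg for a 6.26-Mbp genome
#' @export
dna_mass_per_cell <- function(genome_bp, bp_mass = 650) {
  stopifnot(is.numeric(genome_bp), is.numeric(bp_mass))
  if (any(genome_bp <= 0)) stop("'genome_bp' must be positive")
  if (any(bp_mass <= 0)) stop("'bp_mass' must be positive")
  genome_bp * bp_mass / AVOGADRO * 1e15
}

#' Cells represented by one microgram of genomic DNA
#'
#' The exact inverse of [dna_mass_per_cell()]: `1e9 fg per ug / fg per cell`.
#'
#' @param dna_per_cell_fg DNA mass per cell (fg, > 0).
#' @return Cells per microgram of DNA.
#' @examples
#' cells_per_microgram(dna_mass_per_cell(6.26e6))  # ~1.48e8
#' @export
cells_per_microgram <- function(dna_per_cell_fg) {
  stopifnot(is.numeric(dna_per_cell_fg))
  if (any(dna_per_cell_fg <= 0)) stop("'dna_per_cell_fg' must be positive")
  1e9 / dna_per_cell_fg
}

#' Cell model: genome-derived DNA mass and cell-count equivalents
#'
#' @param genome_bp genome size in base pairs.
#' @param bp_mass average base-pair molar mass (g/mol).
#' @return An object of class `cell_model` with fields `genome_bp`,
#'   `bp_mass`, `dna_per_cell_fg` and `cells_per_ug`.
#' @export
cell_model <- function(genome_bp = 6.26e6, bp_mass = 650) {
  dna_fg <- dna_mass_per_cell(genome_bp, bp_mass)
  structure(list(genome_bp = genome_bp,
                 bp_mass = bp_mass,
                 dna_per_cell_fg = dna_fg,
                 cells_per_ug = cells_per_microgram(dna_fg)),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("Cell model: %.3g bp genome, %.3g fg DNA/cell, %.3g cells/ug DNA\n",
              x$genome_bp, x$dna_per_cell_fg, x$cells_per_ug))
  invisible(x)
}

#' OD-to-biomass conversion factors
#'
#' Holds the empirically determined linear factors converting one absorbance
#' unit at 600 nm to DNA concentration and wet pellet mass per mL of culture;
#' the cells-per-OD factor is derived by chaining the DNA factor with the
#' genome-based cells-per-microgram count.
#'
#' @param dna_per_od ug DNA per mL culture per au (default 6.0).
#' @param pellet_per_od mg wet pellet per mL culture per au (default 3.4).
#' @param model a [cell_model()] supplying `cells_per_ug`.
#' @return An object of class `conversion_factors` with fields `dna_per_od`,
#'   `pellet_per_od`, `cells_per_od`, and the `model` used.
#' @export
conversion_factors <- function(dna_per_od = 6.0, pellet_per_od = 3.4,
                               model = cell_model()) {
  stopifnot(dna_per_od > 0, pellet_per_od > 0, inherits(model, "cell_model"))
  structure(list(dna_per_od = dna_per_od,
                 pellet_per_od = pellet_per_od,
                 cells_per_od = dna_per_od * model$cells_per_ug,
                 model = model),
            class = "conversion_factors")
}

#' Convert an optical density reading to biomass quantities
#'
#' @param od optical density (au, >= 0); vectorized.
#' @param factors a [conversion_factors()] object.
#' @return A data.frame with columns `od`, `dna_ug_per_ml`, `cells_per_ml`
#'   and `pellet_mg_per_ml`.
#' @examples
#' od_to_quantities(1, conversion_factors())
#' @export
od_to_quantities <- function(od, factors = conversion_factors()) {
  stopifnot(is.numeric(od), inherits(factors, "conversion_factors"))
  if (any(od < 0)) stop("'od' must be non-negative")
  dna <- od * factors$dna_per_od
  data.frame(od = od,
             dna_ug_per_ml = dna,
             cells_per_ml = dna * factors$model$cells_per_ug,
             pellet_mg_per_ml = od * factors$pellet_per_od)
}

#' Heme share of total cellular iron
#'
#' Each heme carries one iron atom, so the molar ratio of heme to total iron
#' (both normalized per microgram DNA) is the percentage of cellular iron
#' stored as heme.
#'
#' @param heme_pmol_per_ug heme load (pmol per ug DNA).
#' @param total_fe_pmol_per_ug total iron load (pmol per ug DNA, > 0).
#' @return Percentage, unrounded (display rounding is left to reports).
#' @examples
#' heme_fraction(140, 380)  # ~36.8 %
#' @export
heme_fraction <- function(heme_pmol_per_ug, total_fe_pmol_per_ug) {
  stopifnot(is.numeric(heme_pmol_per_ug), is.numeric(total_fe_pmol_per_ug))
  if (any(total_fe_pmol_per_ug <= 0)) stop("total iron must be positive")
  if (any(heme_pmol_per_ug < 0)) stop("heme load must be non-negative")
  if (any(heme_pmol_per_ug > total_fe_pmol_per_ug * 1.05)) {
    stop("heme exceeds total iron by more than the 5 % measurement allowance")
  }
  100 * heme_pmol_per_ug / total_fe_pmol_per_ug
}

#' Express a growth rate in cells per hour
#'
#' Converts a maximum specific growth rate measured in absorbance units per
#' hour into cells produced per hour per mL culture via the cells-per-OD
#' factor.
#'
#' @param mu_m growth rate (au/h, >= 0).
#' @param factors a [conversion_factors()] object.
#' @return Growth rate in cells/h (per mL culture).
#' @export
rate_to_cells <- function(mu_m, factors = conversion_factors()) {
  stopifnot(is.numeric(mu_m), inherits(factors, "conversion_factors"))
  if (any(mu_m < 0)) stop("'mu_m' must be non-negative")
  mu_m * factors$cells_per_od
}
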