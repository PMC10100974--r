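# Extrapolation of per-ug-DNA metabolite loads to the whole gut microbiome.

#' Microbiome census model
#'
#' Cell census of the reference human gut microbiome used for reservoir
#' extrapolation: 3.8e13 bacterial cells averaging 5 pg wet mass each
#' (roughly 200 g of biomass), treated as if composed entirely of the
#' measured organism so that its genome defines the DNA content.
#'
#' @param n_cells total bacterial cells in the GI tract.
#' @param cell_mass_pg average wet mass per cell (pg).
#' @param model a [cell_model()] for the surrogate organism.
#' @return An object of class `microbiome_model` with the derived
#'   `total_mass_g = n_cells * cell_mass_pg * 1e-12`.
#' @export
microbiome_model <- function(n_cells = 3.8e13, cell_mass_pg = 5,
                             model = cell_model()) {
  stopifnot(n_cells > 0, cell_mass_pg > 0, inherits(model, "cell_model"))
  structure(list(n_cells = n_cells,
                 cell_mass_pg = cell_mass_pg,
                 total_mass_g = n_cells * cell_mass_pg * 1e-12,
                 cell_model = model),
            class = "microbiome_model")
}

#' @export
print.microbiome_model <- function(x, ...) {
  cat(sprintf("Microbiome model: %.3g cells, %.3g pg/cell (~%.0f g total biomass)\n",
              x$n_cells, x$cell_mass_pg, x$total_mass_g))
  invisible(x)
}

#' Total genomic DNA of the modelled microbiome
#'
#' @param model a [microbiome_model()].
#' @return Total DNA in ug: `n_cells * dna_per_cell_fg * 1e-9`.
#' @export
total_microbiome_dna <- function(model = microbiome_model()) {
  stopifnot(inherits(model, "microbiome_model"))
  model$n_cells * model$cell_model$dna_per_cell_fg * 1e-9
}

#' Extrapolate a per-DNA iron load to the whole microbiome
#'
#' Multiplies a measured load (pmol of iron per ug DNA) by the microbiome's
#' total DNA and the molar mass of iron:
#' `mg = pmol_per_ug * total_dna_ug * molar_mass * 1e-9`.
#'
#' @param pmol_per_ug measured load (pmol per ug DNA, >= 0).
#' @param model a [microbiome_model()].
#' @param molar_mass molar mass used for the mass conversion (g/mol);
#'   default elemental iron, 55.845.
#' @return Iron mass in mg.
#' @examples
#' extrapolate_iron(380)  # ~5.5 mg across the gut microbiome
#' @export
extrapolate_iron <- function(pmol_per_ug, model = microbiome_model(),
                             molar_mass = MOLAR_MASS_FE) {
  stopifnot(is.numeric(pmol_per_ug), inherits(model, "microbiome_model"))
  if (any(pmol_per_ug < 0)) stop("'pmol_per_ug' must be non-negative")
  pmol_per_ug * total_microbiome_dna(model) * molar_mass * 1e-9
}

#' Extrapolate the heme-bound iron pool to the whole microbiome
#'
#' Same arithmetic as [extrapolate_iron()]: each heme molecule carries one
#' iron atom, and the result is reported as the iron-equivalent mass of the
#' heme pool (molar mass 55.845 g/mol), not as the mass of the hemin salt.
#'
#' @param heme_pmol_per_ug heme load (pmol per ug DNA, >= 0).
#' @param model a [microbiome_model()].
#' @return Iron-equivalent heme mass in mg.
#' @export
extrapolate_heme_iron <- function(heme_pmol_per_ug, model = microbiome_model()) {
  extrapolate_iron(heme_pmol_per_ug, model, molar_mass = MOLAR_MASS_FE)
}

#' Days of host iron absorption buffered by the microbiome
#'
#' Divides the microbiome iron reservoir by the host's daily absorbed iron
#' (typically 1 to 3 mg/day) to express the reservoir as days of buffer
#' against dietary iron starvation.
#'
#' @param total_iron_mg reservoir size (mg, >= 0).
#' @param daily_absorption_mg absorbed iron per day (mg/day, > 0); may be a
#'   vector (e.g. `c(1, 3)` for a range).
#' @return Days of buffer, one value per absorption rate (named when a
#'   2-element range is given).
#' @export
buffer_days <- function(total_iron_mg, daily_absorption_mg = c(1, 3)) {
  stopifnot(is.numeric(total_iron_mg), is.numeric(daily_absorption_mg))
  if (total_iron_mg < 0) stop("'total_iron_mg' must be non-negative")
  if (any(daily_absorption_mg <= 0)) stop("daily absorption must be positive")
  days <- total_iron_mg / daily_absorption_mg
  if (length(days) == 2L) names(days) <- c("upper", "lower")[order(daily_absorption_mg)]
  days
}

#' Build a reservoir table from per-DNA measurements
#'
#' Takes condition-wise total-iron and heme loads (pmol per ug DNA, with
#' optional standard deviations) and extrapolates each to whole-microbiome
#' masses, propagating the SDs by the same linear scaling.
#'
#' @param measurements a data.frame with columns `condition`,
#'   `total_fe_pmol_per_ug`, `heme_pmol_per_ug` and optionally
#'   `total_fe_sd`, `heme_sd`.
#' @param model a [microbiome_model()].
#' @return A data.frame with columns `condition`, `total_iron_mg`,
#'   `heme_iron_mg` (plus `total_iron_sd_mg`, `heme_iron_sd_mg` when SDs are
#'   supplied) and the attribute `total_dna_ug`.
#' @examples
#' m <- data.frame(condition = c("rich", "hemin"),
#'                 total_fe_pmol_per_ug = c(254, 380),
#'                 heme_pmol_per_ug = c(1.59, 140))
#' reservoir_table(m)
#' @export
reservoir_table <- function(measurements, model = microbiome_model()) {
  need <- c("condition", "total_fe_pmol_per_ug", "heme_pmol_per_ug")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(
    condition = measurements$condition,
    total_iron_mg = extrapolate_iron(measurements$total_fe_pmol_per_ug, model),
    heme_iron_mg = extrapolate_heme_iron(measurements$heme_pmol_per_ug, model))
  if ("total_fe_sd" %in% names(measurements)) {
    out$total_iron_sd_mg <- extrapolate_iron(measurements$total_fe_sd, model)
  }
  if ("heme_sd" %in% names(measurements)) {
    out$heme_iron_sd_mg <- extrapolate_heme_iron(measurements$heme_sd, model)
  }
  attr(out, "total_dna_ug") <- total_microbiome_dna(model)
  out
}
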