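# Raw-signal quantification: linear standard curves, extracted-ion
# chromatograms, peak integration, and normalization to genomic DNA.

MOLAR_MASS_FE <- 55.845  # g/mol

# Accurate masses of the singly protonated ions followed by the LC-MS assay.
#' Target m/z values and default chromatography settings
#'
#' `MZ_HEME` and `MZ_PPIX` are the positive-mode m/z values of heme and
#' protoporphyrin IX (the 282.13 fragment of PPIX is recorded as annotation
#' only and not used for quantification).
#' @name mz-targets
#' @export
MZ_HEME <- 616.17
#' @rdname mz-targets
#' @export
MZ_PPIX <- 563.26
PPIX_FRAGMENT_MZ <- 282.13

#' Fit a linear calibration (standard) curve
#'
#' Least-squares line through signal-versus-concentration standards with a
#' free intercept. The intercept is reported as a quality diagnostic (and can
#' optionally be subtracted during quantification for instruments with a
#' genuine blank offset; see [signal_to_concentration()]). The fit is
#' flagged when linearity is poor (R^2 < 0.99) or the intercept exceeds 5 %
#' of the largest standard signal.
#'
#' @param levels standard concentrations (ppm for atomic absorption, uM for
#'   porphyrins); at least 3 distinct values, all >= 0.
#' @param signals measured responses (absorbance, or integrated ion counts).
#' @param analyte label, e.g. `"total_iron"`, `"heme"`, `"ppix"`.
#' @param unit concentration unit of `levels`: `"uM"` or `"ppm"`.
#' @return An object of class `calibration_curve`: `analyte`, `unit`,
#'   `slope`, `intercept`, `r_squared`, `valid_range`, `flags`.
#' @examples
#' cal <- fit_calibration(c(0.25, 0.5, 1, 2, 4, 6), c(0.25, 0.5, 1, 2, 4, 6) * 5e4,
#'                        analyte = "heme")
#' cal$slope
#' @export
fit_calibration <- function(levels, signals, analyte = "analyte", unit = "uM") {
  stopifnot(is.numeric(levels), is.numeric(signals),
            length(levels) == length(signals))
  if (any(levels < 0)) stop("standard levels must be non-negative")
  if (length(unique(levels)) < 3L) stop("need at least 3 distinct standard levels")
  unit <- match.arg(unit, c("uM", "ppm"))
  fit <- stats::lm(signals ~ levels)
  co <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # silence perfect-fit notice
  flags <- character()
  if (r2 < 0.99) flags <- c(flags, "low_r_squared")
  if (abs(co[["(Intercept)"]]) > 0.05 * max(abs(signals))) {
    flags <- c(flags, "large_intercept")
  }
  if (length(flags)) {
    warning("calibration quality flags for ", analyte, ": ",
            paste(flags, collapse = ", "))
  }
  structure(list(analyte = analyte,
                 unit = unit,
                 slope = unname(co[["levels"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 r_squared = r2,
                 valid_range = range(levels),
                 flags = flags),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration [%s]: signal = %.4g * %s + %.4g (R^2 = %.5f)\n",
              x$analyte, x$slope, x$unit, x$intercept, x$r_squared))
  invisible(x)
}

#' Construct a chromatogram object
#'
#' A chromatogram is stored long-form: one row per (scan time, m/z channel)
#' pair with its intensity, mirroring the on-disk CSV schema.
#'
#' @param scan_time_min scan times (min).
#' @param mz m/z channel of each row (Da).
#' @param intensity ion counts (>= 0).
#' @return A data.frame of class `chromatogram`.
#' @export
chromatogram <- function(scan_time_min, mz, intensity) {
  stopifnot(length(scan_time_min) == length(mz),
            length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  times <- sort(unique(scan_time_min))
  if (any(diff(times) <= 0)) stop("scan times must be strictly increasing")
  out <- data.frame(scan_time_min = scan_time_min, mz = mz,
                    intensity = intensity)
  out <- out[order(out$scan_time_min, out$mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("chromatogram", "data.frame")
  out
}

#' Extract an ion chromatogram for one target mass
#'
#' Sums, scan by scan, the intensities of all m/z channels within
#' `tolerance` of the target mass — the standard EIC operation used to
#' isolate one analyte from a complex total-ion chromatogram.
#'
#' @param chrom a [chromatogram()] object.
#' @param target_mz target mass (Da).
#' @param tolerance half-width of the extraction window (Da, > 0); the
#'   default 0.02 Da reflects Q-TOF-class mass accuracy.
#' @return An object of class `eic_trace`: `target_mz`, `tolerance`, `times`
#'   (min) and `intensities` (counts), one entry per scan.
#' @export
extract_eic <- function(chrom, target_mz, tolerance = 0.02) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (!nrow(chrom)) stop("empty chromatogram")
  if (tolerance <= 0) stop("'tolerance' must be positive")
  times <- sort(unique(chrom$scan_time_min))
  sel <- abs(chrom$mz - target_mz) <= tolerance
  agg <- rep(0, length(times))
  if (any(sel)) {
    sums <- tapply(chrom$intensity[sel], factor(chrom$scan_time_min[sel],
                                                levels = times), sum)
    sums[is.na(sums)] <- 0
    agg <- as.numeric(sums)
  }
  structure(list(target_mz = target_mz, tolerance = tolerance,
                 times = times, intensities = agg),
            class = "eic_trace")
}

#' @export
print.eic_trace <- function(x, ...) {
  cat(sprintf("EIC at m/z %.2f +/- %.3g Da: %d scans, max %.4g counts\n",
              x$target_mz, x$tolerance, length(x$times), max(x$intensities)))
  invisible(x)
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integration of an extracted-ion trace over a retention-time
#' window, after subtracting a constant baseline estimated as the median
#' intensity outside the window (zero when the trace is all inside).
#'
#' @param trace an [extract_eic()] trace.
#' @param window `c(t_start, t_end)` in minutes, within the trace.
#' @return Peak area in counts * min (floored at 0).
#' @export
integrate_peak <- function(trace, window) {
  stopifnot(inherits(trace, "eic_trace"), length(window) == 2L)
  if (window[2] <= window[1]) stop("integration window must have t_end > t_start")
  if (window[1] < min(trace$times) || window[2] > max(trace$times)) {
    stop("integration window extends beyond the trace")
  }
  inside <- trace$times >= window[1] & trace$times <= window[2]
  if (sum(inside) < 2L) stop("integration window contains fewer than 2 scans")
  baseline <- if (any(!inside)) stats::median(trace$intensities[!inside]) else 0
  y <- pmax(trace$intensities[inside] - baseline, 0)
  max(pracma::trapz(trace$times[inside], y), 0)
}

#' Convert an instrument signal to a concentration per mL of culture
#'
#' Applies the calibration line in reverse (`level = signal / slope`, the
#' slope-only conversion used when blanks read zero; set
#' `subtract_intercept = TRUE` for instruments with a genuine blank offset),
#' converts the level to umol/L if the standards were prepared in ppm, then
#' scales by the dilution factor and divides by the culture volume:
#' `conc = level_uM * dilution_factor / culture_volume_ml` (nmol per mL of
#' culture, since 1 uM = 1 nmol/mL). Injections whose back-calculated
#' concentration falls below the detection limit are flagged, not zeroed.
#'
#' @param signal measured response (>= 0 after blank subtraction).
#' @param curve a [fit_calibration()] curve.
#' @param dilution_factor overall dilution applied between culture extract
#'   and measured sample (>= 1).
#' @param culture_volume_ml volume of culture represented by the extract (mL).
#' @param molar_mass analyte molar mass (g/mol), required to convert ppm
#'   standards to molar units; defaults to iron.
#' @param lod_uM detection limit per injection (uM); default 0.25 uM (250 nM).
#' @param subtract_intercept subtract the fitted calibration intercept before
#'   dividing by the slope; default `FALSE` (slope-only conversion).
#' @return A list with `conc_nmol_per_ml`, `injection_uM` and `below_lod`.
#' @export
signal_to_concentration <- function(signal, curve, dilution_factor = 1,
                                    culture_volume_ml = 1,
                                    molar_mass = MOLAR_MASS_FE,
                                    lod_uM = 0.25,
                                    subtract_intercept = FALSE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be positive")
  if (any(signal < 0)) stop("'signal' must be non-negative")
  if (dilution_factor < 1) stop("'dilution_factor' must be >= 1")
  if (culture_volume_ml <= 0) stop("'culture_volume_ml' must be positive")
  offset <- if (subtract_intercept) curve$intercept else 0
  level <- (signal - offset) / curve$slope
  inj_uM <- switch(curve$unit,
                   uM = level,
                   ppm = level * 1000 / molar_mass)
  inj_uM <- pmax(inj_uM, 0)
  list(conc_nmol_per_ml = inj_uM * dilution_factor / culture_volume_ml,
       injection_uM = inj_uM,
       below_lod = inj_uM < lod_uM)
}

#' Normalize a culture concentration to genomic DNA
#'
#' Rescales nmol per mL of culture to pmol per ug of DNA extracted from the
#' same culture, the cell-count surrogate used throughout:
#' `pmol/ug = nmol/mL * 1000 / (ug DNA / mL)`.
#'
#' @param conc_nmol_per_ml analyte concentration (nmol per mL culture).
#' @param dna_ug_per_ml DNA yield of the culture (ug/mL, > 0).
#' @return Analyte load in pmol per ug DNA.
#' @export
normalize_to_dna <- function(conc_nmol_per_ml, dna_ug_per_ml) {
  stopifnot(is.numeric(conc_nmol_per_ml), is.numeric(dna_ug_per_ml))
  if (any(dna_ug_per_ml <= 0)) stop("'dna_ug_per_ml' must be positive")
  if (any(conc_nmol_per_ml < 0)) stop("concentration must be non-negative")
  conc_nmol_per_ml * 1000 / dna_ug_per_ml
}

#' Quantify a simulated (or assembled) culture bundle end to end
#'
#' Runs the full measurement chain on one culture: fit the atomic-absorption
#' and porphyrin standard curves, quantify total iron from the absorbance
#' reading, extract and integrate the heme and PPIX peaks of the sample
#' chromatogram, convert every signal to nmol per mL culture, and normalize
#' to the bundle's DNA yield.
#'
#' @param bundle a [sim_culture_dataset()] bundle (or a list with the same
#'   fields assembled from real measurements).
#' @param mz_tolerance EIC extraction half-width (Da).
#' @param peak_halfwidth_sigmas integration window half-width in units of the
#'   nominal peak sigma.
#' @return A data.frame with one row per analyte (`total_iron`, `heme`,
#'   `ppix`) and columns `conc_nmol_per_ml`, `pmol_per_ug_dna`, `below_lod`.
#' @export
quantify_culture <- function(bundle, mz_tolerance = 0.02,
                             peak_halfwidth_sigmas = 4) {
  stopifnot(is.list(bundle))
  aa_cal <- fit_calibration(bundle$aa$calibration$level,
                            bundle$aa$calibration$signal,
                            analyte = "total_iron", unit = "ppm")
  fe <- signal_to_concentration(mean(bundle$aa$sample_signal), aa_cal,
                                dilution_factor = bundle$aa$dilution_factor,
                                culture_volume_ml = bundle$culture_volume_ml,
                                molar_mass = MOLAR_MASS_FE)

  ms <- bundle$ms
  quant_porphyrin <- function(analyte, target_mz, rt) {
    cal_df <- ms$calibration[[analyte]]
    cal <- fit_calibration(cal_df$level, cal_df$signal, analyte = analyte,
                           unit = "uM")
    trace <- extract_eic(ms$chromatogram, target_mz, tolerance = mz_tolerance)
    hw <- peak_halfwidth_sigmas * ms$peak_sigma_min
    window <- c(max(rt - hw, min(trace$times)), min(rt + hw, max(trace$times)))
    area <- integrate_peak(trace, window)
    signal_to_concentration(area, cal,
                            dilution_factor = ms$dilution_factor,
                            culture_volume_ml = bundle$culture_volume_ml)
  }
  heme <- quant_porphyrin("heme", MZ_HEME, ms$rt_heme_min)
  ppix <- quant_porphyrin("ppix", MZ_PPIX, ms$rt_ppix_min)

  res <- data.frame(
    analyte = c("total_iron", "heme", "ppix"),
    conc_nmol_per_ml = c(fe$conc_nmol_per_ml, heme$conc_nmol_per_ml,
                         ppix$conc_nmol_per_ml),
    below_lod = c(fe$below_lod, heme$below_lod, ppix$below_lod))
  res$pmol_per_ug_dna <- normalize_to_dna(res$conc_nmol_per_ml,
                                          bundle$dna_ug_per_ml)
  res
}
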