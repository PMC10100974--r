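# Synthetic-data generator: plate-reader growth curves, calibration series,
# Q-TOF chromatograms, protein families at controlled identity, operon-bearing
# genome layouts, and whole culture bundles tying them together.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulation configuration
#'
#' Collects the instrument-noise and sampling settings shared by the
#' generators: additive Gaussian noise on OD readings, multiplicative
#' Gaussian noise on instrument signals, and the chromatographic scan grid.
#'
#' @param seed integer seed making every derived dataset reproducible.
#' @param noise_sd_od additive OD noise SD (au).
#' @param noise_rel_signal relative (multiplicative) signal noise, as a
#'   fraction.
#' @param scan_interval_min chromatogram scan spacing (min).
#' @param peak_sigma_min chromatographic peak SD (min).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, noise_sd_od = 0.01, noise_rel_signal = 0.01,
                       scan_interval_min = 0.02, peak_sigma_min = 0.1) {
  stopifnot(noise_sd_od >= 0, noise_rel_signal >= 0,
            scan_interval_min > 0, peak_sigma_min > 0)
  structure(list(seed = as.integer(seed),
                 noise_sd_od = noise_sd_od,
                 noise_rel_signal = noise_rel_signal,
                 scan_interval_min = scan_interval_min,
                 peak_sigma_min = peak_sigma_min),
            class = "sim_config")
}

#' Simulate a plate-reader growth curve
#'
#' Evaluates the modified Gompertz model on a time grid and adds i.i.d.
#' Gaussian reading noise, flooring at zero (optical densities cannot be
#' negative).
#'
#' @param params a [gompertz_params()] object.
#' @param times sampling times (h), strictly increasing, non-empty.
#' @param noise_sd additive noise SD (au, >= 0).
#' @param seed optional seed for reproducibility.
#' @param replicate_id label attached to the curve.
#' @return A data.frame of class `growth_curve` with columns `time_h`, `od`
#'   and `replicate_id`.
#' @examples
#' p <- gompertz_params(1.46, 0.260, 4.94)
#' sim_growth_curve(p, seq(0, 30, 0.5), noise_sd = 0.01, seed = 7)
#' @export
sim_growth_curve <- function(params, times, noise_sd = 0, seed = NULL,
                             replicate_id = "rep1") {
  stopifnot(is.numeric(times))
  if (!length(times)) stop("empty time grid")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  od <- gompertz_od(params, times)
  if (noise_sd > 0) {
    od <- with_seed(seed, od + stats::rnorm(length(times), sd = noise_sd))
  }
  out <- data.frame(time_h = times, od = pmax(od, 0),
                    replicate_id = replicate_id)
  class(out) <- c("growth_curve", "data.frame")
  out
}

#' Simulate a calibration standard series
#'
#' Linear instrument response with multiplicative Gaussian noise:
#' `signal_i = slope * level_i * (1 + eps_i)`, so blanks stay at zero and the
#' relative error is constant across the range, as calibration standards
#' typically behave.
#'
#' @param slope true response factor (signal per concentration unit, > 0).
#' @param levels standard concentrations (>= 0).
#' @param rel_noise relative noise SD (fraction, >= 0).
#' @param seed optional seed.
#' @return A data.frame with columns `level` and `signal`.
#' @export
sim_calibration_series <- function(slope, levels, rel_noise = 0, seed = NULL) {
  stopifnot(is.numeric(slope), is.numeric(levels))
  if (slope <= 0) stop("'slope' must be positive")
  if (any(levels < 0)) stop("standard levels must be non-negative")
  if (rel_noise < 0) stop("'rel_noise' must be non-negative")
  eps <- if (rel_noise > 0) {
    with_seed(seed, stats::rnorm(length(levels), sd = rel_noise))
  } else {
    rep(0, length(levels))
  }
  data.frame(level = levels, signal = slope * levels * (1 + eps))
}

# Default AA (0.1-4 ppm) and porphyrin (0.25-6 uM) standard ladders.
aa_standard_levels <- function() c(0.1, 0.25, 0.5, 1, 1.5, 2, 3, 4)
porphyrin_standard_levels <- function() c(0.25, 0.5, 0.75, 1.5, 3, 6)

#' Simulate a Q-TOF chromatogram with Gaussian elution peaks
#'
#' Builds a dense scan grid (fixed interval) and lays down one Gaussian
#' elution profile per requested peak:
#' `intensity(t) = height * exp(-(t - rt)^2 / (2 sigma_rt^2))` in the peak's
#' own m/z channel. Peaks sharing an m/z channel sum; co-eluting peaks at
#' distinct m/z stay in separate channels.
#'
#' @param peaks a data.frame with columns `mz` (Da, > 0), `rt` (min),
#'   `height` (counts, >= 0) and `sigma_rt` (min, > 0). May have zero rows.
#' @param duration_min run length (min); must cover every `rt +/- 4 sigma`.
#' @param scan_interval_min scan spacing (min).
#' @param noise_rel relative intensity noise (fraction); applied
#'   multiplicatively, floored at zero counts.
#' @param seed optional seed.
#' @return A [chromatogram()] object (long data.frame). When `peaks` is
#'   empty a single all-zero channel at m/z 0 is emitted so the scan grid is
#'   preserved.
#' @export
sim_chromatogram <- function(peaks, duration_min, scan_interval_min = 0.02,
                             noise_rel = 0, seed = NULL) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks)) {
    need <- c("mz", "rt", "height", "sigma_rt")
    if (!all(need %in% names(peaks))) {
      stop("peaks needs columns: ", paste(need, collapse = ", "))
    }
    if (any(peaks$mz <= 0)) stop("peak m/z must be positive")
    if (any(peaks$sigma_rt <= 0)) stop("peak sigma_rt must be positive")
    if (any(peaks$height < 0)) stop("peak height must be non-negative")
    if (any(peaks$rt + 4 * peaks$sigma_rt > duration_min) ||
        any(peaks$rt - 4 * peaks$sigma_rt < 0)) {
      stop("duration does not cover all peaks (need rt +/- 4 sigma inside run)")
    }
  }
  times <- seq(0, duration_min, by = scan_interval_min)
  if (!nrow(peaks)) {
    return(chromatogram(times, rep(0, length(times)), rep(0, length(times))))
  }
  channels <- sort(unique(peaks$mz))
  rows <- lapply(channels, function(ch) {
    intensity <- rep(0, length(times))
    for (p in which(peaks$mz == ch)) {
      intensity <- intensity + peaks$height[p] *
        exp(-(times - peaks$rt[p])^2 / (2 * peaks$sigma_rt[p]^2))
    }
    data.frame(scan_time_min = times, mz = ch, intensity = intensity)
  })
  out <- do.call(rbind, rows)
  if (noise_rel > 0) {
    out$intensity <- with_seed(seed, pmax(
      out$intensity * (1 + stats::rnorm(nrow(out), sd = noise_rel)), 0))
  }
  chromatogram(out$scan_time_min, out$mz, out$intensity)
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a protein family at a controlled percent identity
#'
#' Draws a random ancestor and derives `n_seqs` family members by uniform
#' random substitution (no indels): each site is replaced with a different
#' residue with probability `(100 - target_identity) / 100`, so the realized
#' identity to the ancestor concentrates around the target (within about
#' 3 points for lengths >= 200).
#'
#' @param length sequence length (>= 10 residues).
#' @param target_identity target percent identity to the ancestor, in
#'   `(0, 100]`.
#' @param n_seqs number of derived sequences.
#' @param seed optional seed.
#' @return A named character vector: `ancestor` plus `derived1..n`.
#' @export
sim_protein_family <- function(length, target_identity, n_seqs = 1, seed = NULL) {
  if (length < 10) stop("'length' must be at least 10 residues")
  if (target_identity <= 0 || target_identity > 100) {
    stop("'target_identity' must be in (0, 100]")
  }
  with_seed(seed, {
    anc <- sample(AA_ALPHABET, length, replace = TRUE)
    p_sub <- (100 - target_identity) / 100
    derived <- vapply(seq_len(n_seqs), function(i) {
      s <- anc
      hit <- stats::runif(length) < p_sub
      if (any(hit)) {
        s[hit] <- vapply(s[hit], function(res) {
          sample(setdiff(AA_ALPHABET, res), 1)
        }, character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    stats::setNames(c(paste(anc, collapse = ""), derived),
                    c("ancestor", sprintf("derived%d", seq_len(n_seqs))))
  })
}

# Plausible gene lengths (bp) for the six operon members; HmuR (the
# TonB-dependent receptor) is the largest.
HMU_GENE_LENGTHS <- c(hmuY = 600, hmuR = 2100, hmuS = 1400,
                      hmuT = 1000, hmuU = 700, hmuV = 400)

#' Simulate a genome's hmu gene layout from a conservation pattern
#'
#' Emits gene loci for hmuY, R, S, T, U, V in canonical order following a
#' 6-character pattern over `{0, 1, 2}`: `0` skips the gene, `1` places one
#' copy in the cluster, `2` additionally places a second copy at a distant
#' locus (1 Mbp downstream). `shuffle = TRUE` permutes the within-cluster
#' gene order, breaking synteny while keeping content.
#'
#' @param pattern 6-character string over `{0,1,2}` in hmuYRSTUV order.
#' @param gap_bp intergenic gap inside the cluster (bp).
#' @param contig contig label.
#' @param shuffle permute cluster gene order (uses `seed`).
#' @param seed optional seed (only consulted when shuffling).
#' @param offset_bp start coordinate of the first gene (1-based).
#' @return A data.frame with columns `gene`, `contig`, `start`, `end`,
#'   `strand` (all `+`), coordinates 1-based inclusive.
#' @examples
#' sim_genome_layout("010111")  # HmuY and HmuS missing
#' @export
sim_genome_layout <- function(pattern, gap_bp = 500, contig = "contig_1",
                              shuffle = FALSE, seed = NULL, offset_bp = 1001) {
  if (!is.character(pattern) || length(pattern) != 1L ||
      nchar(pattern) != 6L || grepl("[^012]", pattern)) {
    stop("'pattern' must be a 6-character string over {0,1,2}")
  }
  score <- as.integer(strsplit(pattern, "", fixed = TRUE)[[1]])
  present <- HMU_GENES[score >= 1L]
  if (!length(present)) {
    return(data.frame(gene = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  order_in_cluster <- if (shuffle) {
    with_seed(seed, sample(present))
  } else {
    present
  }
  pos <- offset_bp
  rows <- vector("list", length(order_in_cluster))
  for (i in seq_along(order_in_cluster)) {
    g <- order_in_cluster[i]
    len <- HMU_GENE_LENGTHS[[g]]
    rows[[i]] <- data.frame(gene = g, contig = contig,
                            start = pos, end = pos + len - 1L, strand = "+")
    pos <- pos + len + gap_bp
  }
  out <- do.call(rbind, rows)
  # distant second copies for score-2 genes
  far <- HMU_GENES[score == 2L]
  if (length(far)) {
    fpos <- max(out$end) + 1e6
    for (g in far) {
      len <- HMU_GENE_LENGTHS[[g]]
      out <- rbind(out, data.frame(gene = g, contig = contig,
                                   start = fpos, end = fpos + len - 1L,
                                   strand = "+"))
      fpos <- fpos + len + gap_bp
    }
  }
  rownames(out) <- NULL
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out
}

#' Simulate a complete culture measurement bundle
#'
#' Generates everything one growth-and-measurement campaign produces for a
#' single culture condition: a saturating growth curve, the DNA yield of the
#' saturated culture, an atomic-absorption standard series plus the sample
#' absorbance encoding the true total-iron load, and a porphyrin standard
#' series plus a sample chromatogram whose heme and PPIX peak areas encode
#' the true porphyrin loads. [quantify_culture()] inverts the chain.
#'
#' @param condition label for the growth condition.
#' @param true_values named numeric vector with elements `total_iron`,
#'   `heme`, `ppix` — the true loads in pmol per ug DNA (>= 0).
#' @param config a [sim_config()].
#' @param growth a [gompertz_params()] object for the condition's curve.
#' @param dna_per_od ug DNA per mL per au used to set the DNA yield.
#' @param aa_slope true AA response (absorbance per ppm).
#' @param ms_slope true porphyrin response (area counts per uM).
#' @param culture_volume_ml culture volume represented by the extract (mL).
#' @param dilution_aa,dilution_ms dilution factors for the two assays.
#' @return A list of class `culture_bundle` with fields `condition`,
#'   `true_values`, `growth_curve`, `dna_ug_per_ml`, `culture_volume_ml`,
#'   `aa` (calibration, sample_signal, dilution_factor) and `ms`
#'   (calibration tables, chromatogram, retention times, peak sigma,
#'   dilution_factor).
#' @export
sim_culture_dataset <- function(condition = "MM + 15 uM hemin",
                                true_values = c(total_iron = 380, heme = 140,
                                                ppix = 1.35),
                                config = sim_config(),
                                growth = gompertz_params(1.46, 0.260, 4.94),
                                dna_per_od = 6.0,
                                aa_slope = 0.05,
                                ms_slope = 5e4,
                                culture_volume_ml = 20,
                                dilution_aa = 4,
                                dilution_ms = 6) {
  stopifnot(inherits(config, "sim_config"))
  tv <- true_values[c("total_iron", "heme", "ppix")]
  if (anyNA(tv)) stop("true_values needs elements total_iron, heme, ppix")
  if (any(tv < 0)) stop("true values must be non-negative")

  seed <- config$seed
  times <- seq(0, 30, by = 0.5)
  curve <- sim_growth_curve(growth, times, noise_sd = config$noise_sd_od,
                            seed = seed, replicate_id = condition)
  dna <- growth$A * dna_per_od  # DNA yield of the saturated culture

  # per-mL-culture concentrations implied by the true loads
  conc <- tv * dna * 1e-3  # nmol/mL culture
  rel <- config$noise_rel_signal

  # atomic absorption: sample injected at conc * volume / dilution (uM),
  # converted to ppm for the instrument's calibration scale
  aa_cal <- sim_calibration_series(aa_slope, aa_standard_levels(),
                                   rel_noise = rel, seed = seed + 1L)
  fe_inj_uM <- conc[["total_iron"]] * culture_volume_ml / dilution_aa
  fe_ppm <- fe_inj_uM * MOLAR_MASS_FE / 1000
  fe_sig <- aa_slope * fe_ppm
  if (rel > 0) {
    fe_sig <- with_seed(seed + 2L, fe_sig * (1 + stats::rnorm(1, sd = rel)))
  }

  # LC-MS: peak areas proportional to injected concentration
  heme_cal <- sim_calibration_series(ms_slope, porphyrin_standard_levels(),
                                     rel_noise = rel, seed = seed + 3L)
  ppix_cal <- sim_calibration_series(ms_slope, porphyrin_standard_levels(),
                                     rel_noise = rel, seed = seed + 4L)
  inj_uM <- conc[c("heme", "ppix")] * culture_volume_ml / dilution_ms
  areas <- ms_slope * inj_uM
  if (rel > 0) {
    areas <- with_seed(seed + 5L,
                       pmax(areas * (1 + stats::rnorm(2, sd = rel)), 0))
  }
  sigma <- config$peak_sigma_min
  rt_heme <- 4.0
  rt_ppix <- 5.0
  heights <- areas / (sigma * sqrt(2 * pi))
  peaks <- data.frame(mz = c(MZ_HEME, MZ_PPIX),
                      rt = c(rt_heme, rt_ppix),
                      height = as.numeric(heights),
                      sigma_rt = sigma)
  peaks <- peaks[peaks$height > 0, , drop = FALSE]
  chrom <- sim_chromatogram(peaks, duration_min = 8,
                            scan_interval_min = config$scan_interval_min)

  structure(list(condition = condition,
                 true_values = tv,
                 growth_curve = curve,
                 dna_ug_per_ml = dna,
                 culture_volume_ml = culture_volume_ml,
                 aa = list(calibration = aa_cal,
                           sample_signal = fe_sig,
                           dilution_factor = dilution_aa),
                 ms = list(calibration = list(heme = heme_cal, ppix = ppix_cal),
                           chromatogram = chrom,
                           rt_heme_min = rt_heme,
                           rt_ppix_min = rt_ppix,
                           peak_sigma_min = sigma,
                           dilution_factor = dilution_ms,
                           ppix_fragment_mz = PPIX_FRAGMENT_MZ)),
            class = "culture_bundle")
}
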