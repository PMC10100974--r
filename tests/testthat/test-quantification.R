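# Standard curves, EIC extraction, peak integration and DNA normalization.

test_that("calibration fits recover exact and noisy slopes", {
  lv <- c(0.1, 0.25, 0.5, 1, 1.5, 2, 3, 4)
  cal <- fit_calibration(lv, 0.25 * lv, analyte = "iron", unit = "ppm")
  expect_equal(cal$slope, 0.25, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_length(cal$flags, 0)

  # porphyrin ladder 0.25-6 uM with 1 % noise: slope within 2 %
  plv <- c(0.25, 0.5, 0.75, 1.5, 3, 6)
  noisy <- sim_calibration_series(5e4, plv, rel_noise = 0.01, seed = 31)
  pcal <- fit_calibration(noisy$level, noisy$signal, analyte = "heme")
  expect_equal(pcal$slope, 5e4, tolerance = 0.02)

  expect_error(fit_calibration(c(1, 2), c(1, 2)), "3 distinct")
  expect_error(fit_calibration(rep(1, 4), 1:4), "3 distinct")
  expect_error(fit_calibration(c(-1, 1, 2), c(1, 2, 3)), "non-negative")
  expect_warning(fit_calibration(c(0, 1, 2, 3), c(0.5, 1, 4, 4.2)),
                 "flags")
})

test_that("EIC extraction isolates the requested mass channel", {
  peaks <- data.frame(mz = c(616.17, 563.26), rt = c(4, 5),
                      height = c(1e5, 4e4), sigma_rt = 0.1)
  chrom <- sim_chromatogram(peaks, duration_min = 8)
  heme <- extract_eic(chrom, 616.17, tolerance = 0.02)
  expect_equal(max(heme$intensities), 1e5, tolerance = 1e-6)
  # absent mass -> all-zero trace on the same scan grid
  none <- extract_eic(chrom, 700.00, tolerance = 0.02)
  expect_true(all(none$intensities == 0))
  expect_identical(none$times, heme$times)
  expect_error(extract_eic(chrom, 616.17, tolerance = 0), "positive")
  expect_error(
    extract_eic(chromatogram(numeric(0), numeric(0), numeric(0)), 616.17),
    "empty")
})

test_that("peak integration matches the Gaussian closed form and converges", {
  area_at <- function(dt) {
    chrom <- sim_chromatogram(
      data.frame(mz = 616.17, rt = 4, height = 1e5, sigma_rt = 0.1),
      duration_min = 8, scan_interval_min = dt)
    integrate_peak(extract_eic(chrom, 616.17, 0.02), c(3.6, 4.4))
  }
  a1 <- area_at(0.02)
  expect_equal(a1, 1e5 * 0.1 * sqrt(2 * pi), tolerance = 0.01)
  # quadrature convergence: halving the scan interval barely moves the area
  expect_lt(abs(area_at(0.01) - a1) / a1, 0.005)

  # flat trace integrates to zero; bad windows are rejected
  flat <- extract_eic(sim_chromatogram(data.frame(), 2), 616.17, 0.02)
  expect_equal(integrate_peak(flat, c(0.5, 1.5)), 0)
  tr <- extract_eic(sim_chromatogram(
    data.frame(mz = 616.17, rt = 4, height = 1e5, sigma_rt = 0.1), 8),
    616.17, 0.02)
  expect_error(integrate_peak(tr, c(5, 4)), "t_end > t_start")
  expect_error(integrate_peak(tr, c(-1, 4)), "beyond")
})

test_that("baseline subtraction removes a constant offset", {
  chrom <- sim_chromatogram(
    data.frame(mz = 616.17, rt = 4, height = 1e5, sigma_rt = 0.1),
    duration_min = 8)
  tr <- extract_eic(chrom, 616.17, 0.02)
  shifted <- tr
  shifted$intensities <- tr$intensities + 500  # constant instrument offset
  a0 <- integrate_peak(tr, c(3.6, 4.4))
  a1 <- integrate_peak(shifted, c(3.6, 4.4))
  expect_equal(a1, a0, tolerance = 0.002)
})

test_that("signal-to-concentration follows the calibration arithmetic", {
  cal <- fit_calibration(c(0.25, 0.5, 1, 2, 4, 6), c(0.25, 0.5, 1, 2, 4, 6) * 5e4,
                         analyte = "heme", unit = "uM")
  base <- signal_to_concentration(5e4 * 2, cal, dilution_factor = 1,
                                  culture_volume_ml = 1)
  expect_equal(base$conc_nmol_per_ml, 2, tolerance = 1e-9)
  expect_false(base$below_lod)
  # doubling the dilution factor doubles the culture concentration
  twice <- signal_to_concentration(5e4 * 2, cal, dilution_factor = 2,
                                   culture_volume_ml = 1)
  expect_equal(twice$conc_nmol_per_ml, 4, tolerance = 1e-9)
  # a 0.1 uM injection sits below the 250 nM detection limit
  faint <- signal_to_concentration(5e4 * 0.1, cal)
  expect_true(faint$below_lod)
  expect_gt(faint$conc_nmol_per_ml, 0)  # reported, not zeroed
  expect_error(signal_to_concentration(-1, cal), "non-negative")
  expect_error(signal_to_concentration(1, cal, dilution_factor = 0.5), ">= 1")

  # optional intercept subtraction for blank-offset instruments
  off_cal <- suppressWarnings(  # the deliberate offset trips the quality flag
    fit_calibration(c(0, 1, 2, 4), c(0, 1, 2, 4) * 10 + 3,
                    analyte = "offset", unit = "uM"))
  corrected <- signal_to_concentration(10 * 2 + 3, off_cal,
                                       subtract_intercept = TRUE)
  expect_equal(corrected$conc_nmol_per_ml, 2, tolerance = 1e-9)

  # ppm calibrations convert through the molar mass (1 ppm Fe = 17.9 uM)
  ppm_cal <- fit_calibration(c(0.1, 0.5, 1, 2, 4), c(0.1, 0.5, 1, 2, 4) * 0.05,
                             analyte = "iron", unit = "ppm")
  fe <- signal_to_concentration(0.05 * 1, ppm_cal)
  expect_equal(fe$injection_uM, 1000 / 55.845, tolerance = 1e-9)
})

test_that("DNA normalization rescales culture concentrations", {
  expect_equal(normalize_to_dna(2.28, 6.0), 380, tolerance = 1e-9)
  expect_equal(normalize_to_dna(0, 6.0), 0)
  expect_equal(normalize_to_dna(2.28, 12.0), 190, tolerance = 1e-9)
  expect_error(normalize_to_dna(1, 0), "positive")
})

test_that("end-to-end quantification recovers known truths", {
  truth <- c(total_iron = 380, heme = 140, ppix = 1.35)
  # zero noise: recovery limited only by quadrature (< 1 %)
  clean <- sim_culture_dataset(
    true_values = truth,
    config = sim_config(seed = 3, noise_sd_od = 0, noise_rel_signal = 0))
  q <- quantify_culture(clean)
  got <- setNames(q$pmol_per_ug_dna, q$analyte)
  expect_equal(got[["total_iron"]], 380, tolerance = 1e-6)
  expect_equal(got[["heme"]], 140, tolerance = 0.01)
  expect_equal(got[["ppix"]], 1.35, tolerance = 0.01)

  # default noise: within 5 %
  noisy <- sim_culture_dataset(true_values = truth, config = sim_config(seed = 4))
  qn <- quantify_culture(noisy)
  gotn <- setNames(qn$pmol_per_ug_dna, qn$analyte)
  expect_equal(gotn[["total_iron"]], 380, tolerance = 0.05)
  expect_equal(gotn[["heme"]], 140, tolerance = 0.05)
  expect_equal(gotn[["ppix"]], 1.35, tolerance = 0.05)
})

test_that("quantification is invariant to uniform intensity rescaling", {
  b <- sim_culture_dataset(
    config = sim_config(seed = 6, noise_sd_od = 0, noise_rel_signal = 0))
  q1 <- quantify_culture(b)
  scaled <- b
  scaled$aa$calibration$signal <- b$aa$calibration$signal * 7
  scaled$aa$sample_signal <- b$aa$sample_signal * 7
  scaled$ms$calibration$heme$signal <- b$ms$calibration$heme$signal * 7
  scaled$ms$calibration$ppix$signal <- b$ms$calibration$ppix$signal * 7
  scaled$ms$chromatogram$intensity <- b$ms$chromatogram$intensity * 7
  q7 <- quantify_culture(scaled)
  expect_equal(q7$pmol_per_ug_dna, q1$pmol_per_ug_dna, tolerance = 1e-9)
})
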