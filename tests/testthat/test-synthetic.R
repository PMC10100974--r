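# Synthetic-data generators: closed-form checks, determinism, and the
# statistical structure the downstream analysis assumes.

ref_params <- gompertz_params(1.46, 0.260, 4.94)

test_that("noiseless growth curves equal the closed form and saturate", {
  t <- seq(0, 30, by = 1)
  curve <- sim_growth_curve(ref_params, t, noise_sd = 0)
  expect_equal(curve$od, gompertz_od(ref_params, t), tolerance = 1e-9)
  expect_equal(curve$od[curve$time_h == 30], 1.46, tolerance = 1e-3)
  # at t = lambda the curve passes A * exp(-e)
  at_lag <- sim_growth_curve(ref_params, c(1, 4.94), noise_sd = 0)
  expect_equal(at_lag$od[2], 1.46 * exp(-exp(1)), tolerance = 1e-9)
})

test_that("growth-curve noise is reproducible and floored at zero", {
  t <- seq(0, 30, by = 0.5)
  c1 <- sim_growth_curve(ref_params, t, noise_sd = 0.02, seed = 5)
  c2 <- sim_growth_curve(ref_params, t, noise_sd = 0.02, seed = 5)
  expect_identical(c1, c2)
  c3 <- sim_growth_curve(ref_params, t, noise_sd = 0.02, seed = 6)
  expect_false(identical(c1$od, c3$od))
  # strong noise never drives OD negative
  c4 <- sim_growth_curve(ref_params, t, noise_sd = 0.5, seed = 7)
  expect_true(all(c4$od >= 0))
  expect_error(sim_growth_curve(ref_params, numeric(0)), "empty")
  expect_error(sim_growth_curve(ref_params, t, noise_sd = -1),
               "non-negative")
})

test_that("calibration series are linear with controllable noise", {
  s <- sim_calibration_series(2.0, c(0, 1, 2), rel_noise = 0)
  expect_equal(s$signal, c(0, 2, 4))
  # refitting a noiseless series gives R^2 = 1
  cal <- fit_calibration(s$level, s$signal, analyte = "test")
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$slope, 2.0, tolerance = 1e-12)
  # default AA ladder with 1 % noise recovers the slope within 2 %
  set.seed(1)
  lv <- c(0.1, 0.25, 0.5, 1, 1.5, 2, 3, 4)
  noisy <- sim_calibration_series(0.05, lv, rel_noise = 0.01, seed = 21)
  fit <- fit_calibration(noisy$level, noisy$signal, analyte = "iron",
                         unit = "ppm")
  expect_equal(fit$slope, 0.05, tolerance = 0.02)
  # zero level keeps a zero signal under multiplicative noise
  z <- sim_calibration_series(2.0, c(0, 1), rel_noise = 0.1, seed = 3)
  expect_equal(z$signal[1], 0)
  expect_error(sim_calibration_series(2.0, c(-1, 1)), "non-negative")
  expect_error(sim_calibration_series(-2, c(0, 1)), "positive")
})

test_that("chromatogram peaks have Gaussian closed-form areas", {
  peaks <- data.frame(mz = 616.17, rt = 4, height = 1e5, sigma_rt = 0.1)
  chrom <- sim_chromatogram(peaks, duration_min = 8, scan_interval_min = 0.02)
  trace <- extract_eic(chrom, 616.17, tolerance = 0.02)
  area <- integrate_peak(trace, c(4 - 0.4, 4 + 0.4))
  expect_equal(area, 1e5 * 0.1 * sqrt(2 * pi), tolerance = 0.01)
  expect_error(sim_chromatogram(peaks, duration_min = 4.2), "duration")
})

test_that("empty and multi-analyte chromatograms behave by construction", {
  empty <- sim_chromatogram(data.frame(), duration_min = 2)
  expect_true(all(empty$intensity == 0))
  two <- sim_chromatogram(
    data.frame(mz = c(616.17, 563.26), rt = c(4, 5), height = c(1e5, 5e4),
               sigma_rt = 0.1),
    duration_min = 8)
  heme <- extract_eic(two, 616.17, 0.02)
  ppix <- extract_eic(two, 563.26, 0.02)
  expect_equal(heme$times[which.max(heme$intensities)], 4, tolerance = 0.02)
  expect_equal(ppix$times[which.max(ppix$intensities)], 5, tolerance = 0.02)
  # each EIC contains only its own peak
  expect_equal(max(heme$intensities[heme$times > 4.8]), 0)
  expect_equal(max(ppix$intensities[ppix$times < 4.2]), 0)
  # co-eluting peaks at the same m/z add up
  summed <- sim_chromatogram(
    data.frame(mz = c(616.17, 616.17), rt = c(4, 4), height = c(1e5, 1e5),
               sigma_rt = 0.1),
    duration_min = 8)
  tr <- extract_eic(summed, 616.17, 0.02)
  expect_equal(max(tr$intensities), 2e5, tolerance = 1e-9)
})

test_that("protein families realize their target identity", {
  # full identity -> clones
  fam100 <- sim_protein_family(120, 100, n_seqs = 3, seed = 1)
  expect_true(all(fam100 == fam100[["ancestor"]]))
  # moderate divergence lands near the target (binomial concentration)
  fam40 <- sim_protein_family(300, 40, n_seqs = 3, seed = 8)
  ids <- vapply(fam40[-1], hamming_identity, numeric(1),
                b = fam40[["ancestor"]])
  expect_true(all(ids >= 37 & ids <= 43))
  # determinism and argument validation
  expect_identical(sim_protein_family(50, 80, 2, seed = 4),
                   sim_protein_family(50, 80, 2, seed = 4))
  expect_error(sim_protein_family(5, 50), "at least 10")
  expect_error(sim_protein_family(100, 0), "target_identity")
  expect_error(sim_protein_family(100, 101), "target_identity")
})

test_that("genome layouts follow the conservation pattern string", {
  full <- sim_genome_layout("111111", gap_bp = 500)
  expect_equal(nrow(full), 6)
  expect_identical(full$gene, HMU_GENES)
  # intergenic gaps equal the requested spacing
  gaps <- full$start[-1] - full$end[-6] - 1L
  expect_true(all(gaps == 500))

  partial <- sim_genome_layout("010111")
  expect_identical(partial$gene, c("hmuR", "hmuT", "hmuU", "hmuV"))

  dup <- sim_genome_layout("211111")
  expect_equal(nrow(dup), 7)
  expect_equal(sum(dup$gene == "hmuY"), 2)
  # the second copy sits far from the cluster
  ycopies <- dup[dup$gene == "hmuY", ]
  expect_gt(max(ycopies$start) - min(ycopies$start), 5e5)

  shuf <- sim_genome_layout("111111", shuffle = TRUE, seed = 9)
  expect_setequal(shuf$gene, HMU_GENES)
  expect_false(identical(shuf$gene, HMU_GENES))

  expect_error(sim_genome_layout("11111"), "6-character")
  expect_error(sim_genome_layout("113111"), "6-character")
})

test_that("culture bundles are deterministic under a fixed config", {
  cfg <- sim_config(seed = 13)
  b1 <- sim_culture_dataset(config = cfg)
  b2 <- sim_culture_dataset(config = cfg)
  expect_identical(b1, b2)
  b3 <- sim_culture_dataset(config = sim_config(seed = 14))
  expect_false(identical(b1$aa$sample_signal, b3$aa$sample_signal))
})

test_that("culture bundle signals encode the true analyte loads", {
  # 380 pmol/ug at 6 ug DNA/mL -> 2.28 nmol iron per mL culture
  b <- sim_culture_dataset(
    true_values = c(total_iron = 380, heme = 140, ppix = 1.35),
    config = sim_config(seed = 2, noise_sd_od = 0, noise_rel_signal = 0),
    dna_per_od = 6.0 / 1.46)  # saturated DNA yield of exactly 6 ug/mL
  expect_equal(b$dna_ug_per_ml, 6.0, tolerance = 1e-12)
  aa_cal <- fit_calibration(b$aa$calibration$level, b$aa$calibration$signal,
                            unit = "ppm")
  fe <- signal_to_concentration(b$aa$sample_signal, aa_cal,
                                dilution_factor = b$aa$dilution_factor,
                                culture_volume_ml = b$culture_volume_ml)
  expect_equal(fe$conc_nmol_per_ml, 2.28, tolerance = 1e-6)
  # all-zero truths give an empty-signal bundle
  z <- sim_culture_dataset(
    true_values = c(total_iron = 0, heme = 0, ppix = 0),
    config = sim_config(seed = 2, noise_sd_od = 0, noise_rel_signal = 0))
  qz <- quantify_culture(z)
  expect_equal(qz$pmol_per_ug_dna, c(0, 0, 0), tolerance = 1e-9)
  expect_true(all(qz$below_lod))
  expect_error(
    sim_culture_dataset(true_values = c(total_iron = -1, heme = 0, ppix = 0)),
    "non-negative")
})
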