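test_that("identical config and seed reproduce spectra bit-for-bit", {
  cfg <- sim_config(n_samples = 12, n_wavelengths = 128, seed = 7)
  a <- simulate_spectra(cfg)
  b <- simulate_spectra(cfg)
  expect_identical(a$spectra$intensities, b$spectra$intensities)
  expect_identical(a$reference, b$reference)
  expect_identical(a$truth$per_sample_ssc, b$truth$per_sample_ssc)
})

test_that("config validation errors name the offending field", {
  expect_error(sim_config(n_wavelengths = 1), "n_wavelengths")
  expect_error(sim_config(wl_min = 900, wl_max = 800), "wl_min")
  expect_error(sim_config(band_centers = c(100, 910, 960)), "band_centers")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(band_widths = c(15, 15)), "band_widths")
  expect_error(sim_config(frames_per_sample = 0), "frames_per_sample")
})

test_that("with all noise off, absorbance equals the Beer-Lambert sum exactly", {
  cfg <- sim_config(n_samples = 8, n_wavelengths = 256, noise_sd = 0,
                    scatter_mult_sd = 0, scatter_add_sd = 0, path_sd = 0,
                    path_factor = 1, seed = 3)
  g <- simulate_spectra(cfg)
  A <- to_absorbance(g$spectra, lamp_envelope(cfg))
  expected <- g$truth$concentrations %*% band_profiles(cfg)
  expect_lt(max(abs(A$intensities - expected)), 1e-10)
})

test_that("noise-free single-band problem: 1-LV PLSR recovers the generating slope", {
  cfg <- sim_config(n_samples = 20, n_wavelengths = 128, noise_sd = 0,
                    scatter_mult_sd = 0, scatter_add_sd = 0, path_sd = 0,
                    ref_noise_sd = 0, band_centers = 800, band_widths = 20,
                    band_amplitudes = 0.3, seed = 5)
  g <- simulate_spectra(cfg)
  A <- to_absorbance(g$spectra, lamp_envelope(cfg))
  # absorbance is exactly c1 * g(wl); regressing y on the band sum is exact
  band_sum <- rowSums(A$intensities)
  fit <- pls_fit(matrix(band_sum), g$reference$ssc_percent, 1)
  slope_true <- cfg$ssc_slope / sum(band_profiles(cfg))
  expect_lt(abs(fit$regression_vector - slope_true) / slope_true, 1e-8)
})

test_that("low-noise three-band problem is well calibrated on a held-out quarter", {
  cfg <- sim_config(n_samples = 96, n_wavelengths = 512, noise_sd = 5,
                    scatter_mult_sd = 0, scatter_add_sd = 0, path_sd = 0,
                    ref_noise_sd = 0.05, seed = 17)
  g <- simulate_spectra(cfg)
  A <- to_absorbance(g$spectra, lamp_envelope(cfg))
  sp <- split_calibration_prediction(A, g$reference, "3:1", seed = 2)
  cv <- pls_rmsecv(sp$cal$spectra, sp$cal$reference$ssc_percent, max_lv = 8)
  fit <- pls_fit(sp$cal$spectra, sp$cal$reference$ssc_percent, cv$chosen_lv)
  m <- pls_evaluate(sp$pred$reference$ssc_percent,
                    predict(fit, sp$pred$spectra))
  expect_gt(m$r, 0.95)
  # independent oracle: ordinary least squares on the three true band sums
  feats <- function(set) vapply(g$truth$informative_ranges, function(r)
    rowSums(set$intensities[, r[["start"]]:r[["end"]], drop = FALSE]),
    numeric(nrow(set$intensities)))
  ols <- stats::lm.fit(cbind(1, feats(sp$cal$spectra)),
                       sp$cal$reference$ssc_percent)
  pred <- cbind(1, feats(sp$pred$spectra)) %*% ols$coefficients
  expect_gt(pls_evaluate(sp$pred$reference$ssc_percent, pred)$r, 0.95)
})

test_that("multiframe stacks reduce to the single-frame generator when F = 1", {
  cfg <- sim_config(n_samples = 6, n_wavelengths = 128, seed = 9,
                    frames_per_sample = 1)
  g <- simulate_spectra(cfg)
  fs <- simulate_multiframe(cfg)
  stacked <- t(vapply(fs$frames, function(f) f[1, ], numeric(128)))
  expect_equal(unname(stacked), unname(g$spectra$intensities))
  expect_identical(fs$reference$ssc_percent, g$reference$ssc_percent)
})

test_that("edge frames are brighter and middle frames average to the base spectrum", {
  cfg <- sim_config(n_samples = 6, n_wavelengths = 128, seed = 9,
                    frames_per_sample = 5)
  fs <- simulate_multiframe(cfg)
  for (fm in fs$frames) {
    tot <- rowSums(fm)
    expect_true(all(tot[c(1, 5)] > max(tot[2:4])))
  }
  g <- simulate_spectra(sim_config(n_samples = 6, n_wavelengths = 128, seed = 9))
  mid_avg <- t(vapply(fs$frames, function(f) colMeans(f[2:4, ]), numeric(128)))
  # same clean signal, different noise draws: agree within a few noise sds
  tol <- 5 * cfg$noise_sd
  expect_lt(max(abs(mid_avg - g$spectra$intensities)), tol)
})

test_that("generated SSC is positive and equals the affine map of band-1 concentration", {
  g <- simulate_spectra(sim_config(n_samples = 40, n_wavelengths = 64, seed = 21))
  expect_true(all(g$reference$ssc_percent > 0))
  tr <- g$truth
  expect_equal(tr$per_sample_ssc,
               tr$ssc_relation$intercept +
                 tr$ssc_relation$slope * tr$concentrations[, 1])
  expect_true(all(tr$informative_indices >= 1 & tr$informative_indices <= 64))
})

test_that("path factor scales intensity but SNV output is invariant to it", {
  base <- sim_config(n_samples = 8, n_wavelengths = 128, seed = 13,
                     path_factor = 1, scatter_add_sd = 0, noise_sd = 0)
  hi <- sim_config(n_samples = 8, n_wavelengths = 128, seed = 13,
                   path_factor = 2.5, scatter_add_sd = 0, noise_sd = 0)
  g1 <- simulate_spectra(base); g2 <- simulate_spectra(hi)
  expect_equal(g2$spectra$intensities, 2.5 * g1$spectra$intensities)
  expect_equal(snv(g2$spectra)$intensities, snv(g1$spectra)$intensities,
               tolerance = 1e-12)
})

test_that("spectrum and reference CSV round trips preserve the data", {
  g <- simulate_spectra(sim_config(n_samples = 5, n_wavelengths = 32, seed = 2))
  fs <- tempfile(fileext = ".csv"); fr <- tempfile(fileext = ".csv")
  write_spectra(g$spectra, fs); write_reference(g$reference, fr)
  s2 <- read_spectra(fs); r2 <- read_reference(fr)
  expect_equal(s2$wavelengths, g$spectra$wavelengths)
  expect_equal(s2$intensities, g$spectra$intensities, tolerance = 1e-8)
  expect_equal(r2$ssc_percent, g$reference$ssc_percent, tolerance = 1e-8)
  unlink(c(fs, fr))
})
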