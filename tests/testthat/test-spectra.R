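test_that("RMS normalisation gives every spectrum unit RMS", {
  msi <- rms_normalize(small_msi())
  rms <- sqrt(rowMeans(msi$intensities^2))
  expect_equal(rms, rep(1, nrow(msi$spots)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(msi$normalization, "rms")
})

test_that("normalising twice is refused and zero spectra are left alone", {
  msi <- small_msi()
  expect_error(rms_normalize(rms_normalize(msi)), "twice")
  msi$intensities[2, ] <- 0
  expect_warning(out <- rms_normalize(msi), "all-zero")
  expect_equal(unname(out$intensities[2, 1]), 0)
})

test_that("mean_spectrum averages the selected spots", {
  msi <- small_msi()
  ms <- mean_spectrum(msi, c(1, 3))
  expect_equal(ms$intensity,
               colMeans(msi$intensities[c(1, 3), ]), ignore_attr = TRUE)
  ms2 <- mean_spectrum(msi, msi$spots[2, c("x", "y")])
  expect_equal(ms2$intensity, msi$intensities[2, ], ignore_attr = TRUE)
  expect_error(mean_spectrum(msi, data.frame(x = 99, y = 99)), "absent")
})

test_that("pick_peaks finds a lone strong peak at the right m/z", {
  mz <- seq(700, 900, by = 0.05)
  set.seed(21)
  y <- plant_spectrum(mz, 800.13, 30)
  pk <- pick_peaks(mz, y)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$mz - 800.13), 0.05)
  expect_gt(pk$snr, 6)
})

test_that("pick_peaks applies the relative-intensity gate", {
  mz <- seq(700, 900, by = 0.05)
  set.seed(22)
  # second peak passes S/N but sits below 0.3% of the base peak
  y <- plant_spectrum(mz, c(750.2, 850.4), c(5000, 3), noise_sd = 0.2)
  pk <- pick_peaks(mz, y)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$mz - 750.2), 0.05)
})

test_that("min apex separation keeps only the stronger of close candidates", {
  mz <- seq(700, 760, by = 0.05)
  set.seed(23)
  y <- plant_spectrum(mz, c(730.0, 730.1), c(30, 20), noise_sd = 0.05)
  pk <- pick_peaks(mz, y, min_sep_da = 0.25)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$mz - 730.0), 0.06)
})

test_that("match_peaks pairs within tolerance one-to-one", {
  a <- c(800.000, 900.000, 1000.000)
  b <- c(800.004, 1000.030, 1100.000)   # 5 ppm, 30 ppm, absent
  m <- match_peaks(a, b, tol_ppm = 20)
  expect_equal(nrow(m$common), 1)
  expect_equal(m$common$mz_a, 800.000)
  expect_setequal(m$only_a, c(900, 1000))
  expect_setequal(m$only_b, c(1000.03, 1100))
})

test_that("extract_intensity_matrix recovers planted per-spot amplitudes", {
  mz <- seq(700, 900, by = 0.05)
  amps <- c(10, 20, 40)
  set.seed(24)
  ints <- t(sapply(amps, function(a)
    plant_spectrum(mz, 801.3, a, noise_sd = 0)))
  msi <- msi_dataset(data.frame(x = 0:2, y = 0), mz, ints)
  m <- extract_intensity_matrix(msi, 801.3, tol_ppm = 50)
  expect_equal(as.numeric(m), amps, tolerance = 0.05)
})

test_that("narrow ppm windows fall back to the nearest m/z bin", {
  mz <- seq(700, 900, by = 0.05)
  set.seed(25)
  ints <- rbind(plant_spectrum(mz, 800.125, 25, noise_sd = 0))
  msi <- msi_dataset(data.frame(x = 0, y = 0), mz, ints)
  # 5 ppm of 800 = 0.004 Da << 0.05 Da grid: window is empty
  m <- extract_intensity_matrix(msi, 800.125, tol_ppm = 5)
  expect_gt(m[1, 1], 10)
  expect_warning(extract_intensity_matrix(msi, 5000), "dropped")
})
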