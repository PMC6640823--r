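test_that("absorbance follows the -log10 ratio and inverts exactly", {
  wl <- 450:650
  I0 <- optical_spectrum(wl, rep(1000, length(wl)), kind = "reference")
  same <- optical_spectrum(wl, rep(1000, length(wl)), kind = "raw")
  expect_equal(absorbance(same, I0)$value, rep(0, length(wl)),
               tolerance = 1e-12)
  decade <- optical_spectrum(wl, rep(100, length(wl)), kind = "raw")
  expect_equal(absorbance(decade, I0)$value, rep(1, length(wl)),
               tolerance = 1e-12)
  # round trip A -> I = I0 10^-A -> absorbance recovers A
  set.seed(4)
  A <- runif(length(wl), 0, 2)
  I <- optical_spectrum(wl, 1000 * 10^(-A), kind = "raw")
  expect_equal(absorbance(I, I0)$value, A, tolerance = 1e-12)
})

test_that("absorbance is additive over stacked attenuations and flags bad bins", {
  wl <- 500:600
  I0 <- optical_spectrum(wl, 500 + 5 * (wl - 500), kind = "reference")
  A1 <- 0.3 + 0.002 * (wl - 500)
  A2 <- 0.5 - 0.001 * (wl - 500)
  I <- optical_spectrum(wl, I0$value * 10^(-A1) * 10^(-A2), kind = "raw")
  expect_equal(absorbance(I, I0)$value, A1 + A2, tolerance = 1e-10)
  # zero sample bins are flagged missing, not fabricated
  v <- I0$value; v[10] <- 0
  I2 <- optical_spectrum(wl, v, kind = "raw")
  expect_true(is.na(absorbance(I2, I0)$value[10]))
  # non-positive reference is an error
  bad_ref <- optical_spectrum(wl, c(0, I0$value[-1]), kind = "reference")
  expect_error(absorbance(I, bad_ref), "reference")
})

test_that("band normalization is idempotent, scale-invariant and unit-peak", {
  wl <- 450:650
  const <- optical_spectrum(wl, rep(2.5, length(wl)), kind = "absorbance")
  n1 <- normalize_band(const)
  expect_equal(n1$value, rep(1, length(wl)))
  gauss <- optical_spectrum(wl, exp(-((wl - 550) / 15)^2), kind = "absorbance")
  n2 <- normalize_band(gauss)
  expect_equal(max(n2$value[wl >= 500 & wl <= 600]), 1)
  expect_equal(n2$value[wl == 550], 1)
  # scaling the input by k > 0 leaves the output unchanged; idempotent
  scaled <- optical_spectrum(wl, 37 * gauss$value, kind = "absorbance")
  expect_equal(normalize_band(scaled)$value, n2$value, tolerance = 1e-12)
  expect_equal(normalize_band(n2)$value, n2$value, tolerance = 1e-12)
  expect_error(normalize_band(gauss, band = c(900, 950)), "band")
})

test_that("band peaks are found where constructed, none on monotone spectra", {
  wl <- 450:650
  mono <- optical_spectrum(wl, 0.01 * (wl - 450), kind = "absorbance")
  expect_equal(nrow(band_peaks(mono)), 0)
  two <- optical_spectrum(
    wl, exp(-((wl - 545) / 8)^2) + exp(-((wl - 578) / 8)^2),
    kind = "absorbance")
  pk <- band_peaks(two, band = c(500, 600), min_prominence = 0.05)
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$wavelength_nm[1] - 545), 1.01)
  expect_lt(abs(pk$wavelength_nm[2] - 578), 1.01)
  one <- optical_spectrum(wl, exp(-((wl - 550) / 10)^2), kind = "absorbance")
  pk1 <- band_peaks(one)
  expect_equal(nrow(pk1), 1)
  expect_lt(abs(pk1$wavelength_nm - 550), 1.01)
})

test_that("peak positions agree with an independent peak finder", {
  skip_if_not_installed("pracma")
  wl <- seq(450, 650, by = 0.5)
  set.seed(17)
  v <- exp(-((wl - 542) / 9)^2) + 0.8 * exp(-((wl - 577) / 10)^2) +
    0.02 * sin(wl / 3)
  A <- optical_spectrum(wl, v, kind = "absorbance")
  mine <- band_peaks(A, band = c(500, 600), min_prominence = 0.2)
  sel <- wl >= 500 & wl <= 600
  ref <- pracma::findpeaks(v[sel], minpeakheight = 0.3)
  ref_wl <- sort(wl[sel][ref[, 2]])
  expect_equal(mine$wavelength_nm, ref_wl, tolerance = 1e-9)
})

test_that("spectrum validation catches malformed inputs", {
  expect_error(optical_spectrum(c(1, 2, 2), c(1, 2, 3)), "increasing")
  expect_error(optical_spectrum(1:3, c(1, -2, 3), kind = "raw"),
               "non-negative")
  expect_error(optical_spectrum(1:3, 1:2), "length")
})
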