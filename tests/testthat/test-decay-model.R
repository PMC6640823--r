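test_that("periodic pile-up factor matches limits and brute-force pulse train", {
  # tau << T: correction negligible
  expect_equal(periodic_decay_factor(1, 50), 1, tolerance = 1e-12)
  # tau = T: closed form 1/(1 - e^-1)
  expect_equal(periodic_decay_factor(50, 50), 1 / (1 - exp(-1)),
               tolerance = 1e-12)
  # brute-force summation of 200 shifted exponential pulses, over tau/T grid
  brute <- function(tau, T, K = 200) sum(exp(-(0:K) * T / tau))
  for (ratio in c(0.01, 0.05, 0.1, 0.5, 1, 2)) {
    tau <- ratio * 50
    expect_equal(periodic_decay_factor(tau, 50), brute(tau, 50),
                 tolerance = 1e-10)
  }
  expect_error(periodic_decay_factor(-1, 50), "positive")
  expect_error(periodic_decay_factor(1, 0), "positive")
})

test_that("model curve honours constant limit, degeneracy and linearity", {
  grid <- (0:1023) * 48.8 / 1000
  # tau -> Inf surrogate: flat curve (residual slope is T/tau = 5e-5 at
  # tau = 1e6 ns; essentially exact at 1e9 ns)
  flat <- model_curve(decay_params(1, 1e6), grid, 50)
  expect_lt(diff(range(flat)) / mean(flat), 1e-4)
  flat9 <- model_curve(decay_params(1, 1e9), grid, 50)
  expect_lt(diff(range(flat9)) / mean(flat9), 1e-6)
  # alpha2 = 0 degenerates to the single-component curve
  two <- model_curve(decay_params(c(1, 0), c(0.5, 3)), grid, 50)
  one <- model_curve(decay_params(1, 0.5), grid, 50)
  expect_equal(two, one, tolerance = 1e-14)
  # bin-wise linearity of components
  a <- model_curve(decay_params(1, 0.5), grid, 50)
  b <- model_curve(decay_params(0.5, 3), grid, 50)
  ab <- model_curve(decay_params(c(1, 0.5), c(0.5, 3)), grid, 50)
  expect_equal(ab, a + b, tolerance = 1e-12)
})

test_that("IRF convolution is identity for a delta kernel and conserves counts", {
  set.seed(7)
  curve <- rexp(512, 1)
  expect_equal(convolve_irf(curve, delta_kernel(512)), curve,
               tolerance = 1e-9)
  kern <- dnorm(1:512, 60, 8)
  kern <- kern / sum(kern)
  out <- convolve_irf(curve, kern)
  expect_equal(sum(out), sum(curve), tolerance = 1e-9)
})

test_that("FFT circular convolution agrees with direct O(N^2) summation", {
  set.seed(11)
  n <- 1024L
  curve <- rexp(n, 1)
  kern <- dnorm(seq_len(n), 100, 12)
  kern <- kern / sum(kern)
  direct <- numeric(n)
  for (m in seq_len(n)) {
    j <- seq_len(n)
    direct[m] <- sum(curve[j] * kern[((m - j) %% n) + 1L])
  }
  fftv <- convolve_irf(curve, kern)
  expect_lt(max(abs(fftv - direct)) / max(abs(direct)), 1e-8)
})

test_that("sub-bin IRF shift interpolates linearly and errors on grid mismatch", {
  kern <- delta_kernel(128)
  out <- convolve_irf(delta_kernel(128), kern, irf_shift_ps = 75,
                      bin_width_ps = 50)
  # 1.5-bin shift of a delta: split between bins 2 and 3 (0-based 1 and 2)
  expect_equal(out[2], 0.5, tolerance = 1e-9)
  expect_equal(out[3], 0.5, tolerance = 1e-9)
  expect_error(convolve_irf(rep(1, 100), kern), "grids")
})

test_that("mean lifetime follows the intensity-weighted formula and its bounds", {
  expect_equal(mean_lifetime(decay_params(c(1, 0), c(2, 5))), 2)
  expect_equal(mean_lifetime(decay_params(c(1, 1), c(1, 3))), 2.5)
  # property over random valid parameter sets
  set.seed(3)
  for (i in 1:50) {
    a <- runif(2, 0.01, 5)
    tau <- sort(runif(2, 0.05, 10))
    tm <- mean_lifetime(a, tau)
    expect_gte(tm, tau[1])
    expect_lte(tm, tau[2])
    # >= amplitude-weighted mean
    expect_gte(tm, sum(a * tau) / sum(a) - 1e-12)
    # invariant to overall amplitude scaling
    expect_equal(tm, mean_lifetime(7.3 * a, tau), tolerance = 1e-12)
  }
  expect_error(mean_lifetime(c(0, 0), c(1, 2)), "zero")
})

test_that("intensity fractions sum to one and weight by alpha*tau", {
  f <- intensity_fractions(decay_params(c(2, 1), c(0.5, 3)))
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_equal(f[1], 2 * 0.5 / (2 * 0.5 + 1 * 3), tolerance = 1e-12)
})

test_that("reduced chi-squared matches hand computation and Poisson calibration", {
  expect_equal(reduced_chi2(c(5, 9), c(5, 9), 0), 0)
  expect_equal(reduced_chi2(c(4, 9), c(2, 12), 0), 1.0)
  expect_error(reduced_chi2(1:3, 1:4, 0), "length")
  expect_error(reduced_chi2(1:3, 1:3, 3), "smaller")
  # Poisson data around a known expectation: statistic calibrates near 1
  # (bins kept at >= ~15 expected counts so the max(obs,1) floor is inert)
  grid <- (0:1023) * 48.8 / 1000
  mu <- model_curve(decay_params(1500, 8), grid, 50) + 5
  set.seed(21)
  chis <- replicate(50, reduced_chi2(rpois(length(mu), mu), mu, 0))
  expect_gt(median(chis), 0.8)
  expect_lt(median(chis), 1.2)
})

test_that("decay parameter validation enforces the domain invariants", {
  expect_error(decay_params(c(1, 1), c(1, -2)), "positive")
  expect_error(decay_params(-1, 1), "non-negative")
  expect_error(decay_params(numeric(0), numeric(0)), "components")
  expect_error(decay_params(1, 1, afterpulse_prob = 0.5), "0.2")
  # components stored sorted ascending: tau1 is always the short one
  p <- decay_params(c(1, 2), c(3, 0.5))
  expect_equal(p$tau_ns, c(0.5, 3))
  expect_equal(p$alpha, c(2, 1))
})
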