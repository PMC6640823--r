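test_that("simulated IRF matches the Gaussian x exponential construction", {
  cfg <- sim_config()
  irf <- simulate_irf(cfg, noiseless = TRUE)
  # direct numeric convolution oracle on the same grid
  t <- time_grid(irf)
  sigma <- 300 / 1000 / (2 * sqrt(2 * log(2)))
  g <- dnorm(t, 5, sigma); g <- g / sum(g)
  e <- exp(-t / 0.2)
  n <- length(t)
  direct <- numeric(n)
  for (m in seq_len(n))
    direct[m] <- sum(e[seq_len(n)] * g[((m - seq_len(n)) %% n) + 1L])
  direct <- pmax(direct, 0); direct <- direct / sum(direct)
  scale <- cfg$irf_total_counts - n * cfg$dark_offset
  expected <- direct * scale + cfg$dark_offset
  expect_lt(max(abs(expected - irf$counts)) / max(expected), 1e-8)
  # peak within the first quarter of the window
  expect_lt(which.max(irf$counts), n / 4)
})

test_that("near-delta IRF limit concentrates the counts", {
  cfg <- sim_config(irf_fwhm_ps = 48.8, irf_reference_lifetime_ps = 0,
                    dark_offset = 0)
  irf <- simulate_irf(cfg, noiseless = TRUE)
  pk <- which.max(irf$counts)
  frac3 <- sum(irf$counts[(pk - 1):(pk + 1)]) / sum(irf$counts)
  expect_gte(frac3, 0.99)
})

test_that("IRF simulation is seed-deterministic", {
  cfg <- sim_config()
  a <- simulate_irf(cfg, seed = 10)
  b <- simulate_irf(cfg, seed = 10)
  c <- simulate_irf(cfg, seed = 11)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, c$counts))
})

test_that("noiseless simulated decay equals the fitter's model prediction", {
  # the simulator uses pulse-train summation + stats::convolve; the fitter
  # path uses the closed-form factor + package FFT reconvolution
  cfg <- sim_config()
  irf <- gaussian_irf(cfg)
  tp <- decay_params(c(0.6, 0.4), c(0.5, 3))
  h <- simulate_decay(tp, irf, cfg, channel = 4L, noiseless = TRUE)
  kern <- prepare_irf(irf)
  conv <- pmax(convolve_irf(model_curve(tp, time_grid(h), 50), kern), 0)
  n <- cfg$n_bins
  target <- (5e4 - n * cfg$dark_offset) / (1 + cfg$afterpulse_prob)
  conv <- conv * target / sum(conv)
  pred <- conv + cfg$afterpulse_prob * sum(conv) / n + cfg$dark_offset
  expect_lt(max(abs(pred - h$counts)), 1e-9)
})

test_that("realized totals follow the Poisson budget and decays are reproducible", {
  cfg <- small_config()
  irf <- gaussian_irf(cfg)
  tp <- decay_params(c(0.75, 0.25), c(0.4, 2.7))
  totals <- vapply(1:100, function(i)
    sum(simulate_decay(tp, irf, cfg, seed = substream(3, i),
                       channel = 4L)$counts), numeric(1))
  expect_lt(abs(mean(totals) - 5e4), 5 * sqrt(5e4))
  expect_true(all(abs(totals - 5e4) < 5 * sqrt(5e4) + 3 * sqrt(5e4)))
  a <- simulate_decay(tp, irf, cfg, seed = 77, channel = 4L)
  b <- simulate_decay(tp, irf, cfg, seed = 77, channel = 4L)
  expect_identical(a$counts, b$counts)
})

test_that("round trip: fitting simulated decays recovers the mean lifetime", {
  truth <- decay_params(c(0.75, 0.25), c(0.45, 2.7))
  rec <- recover_lifetimes(truth, n_components = 2, n_rep = 20, seed = 13)
  tm <- mean_lifetime(truth)
  expect_lt(abs(mean(rec$tau_mean) - tm) / tm, 0.05)
})

test_that("reflectance simulator reproduces the constructed chromophore peaks", {
  # zero weights, noiseless: absorbance identically zero
  z <- simulate_reflectance(c(oxy = 0), noise_sd = 0)
  expect_lt(max(abs(absorbance(z$sample, z$reference)$value)), 1e-12)
  # oxy-only mixture: double peak at 542 / 577 nm
  oxy <- simulate_reflectance(c(oxy = 1), noise_sd = 0)
  A <- absorbance(oxy$sample, oxy$reference)
  pk <- band_peaks(A, band = c(500, 600), min_prominence = 0.05)
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$wavelength_nm[1] - 542), 2.01)
  expect_lt(abs(pk$wavelength_nm[2] - 577), 2.01)
  # cytochrome-c-dominated mixture: tallest normalized peak at 550 nm
  cyt <- simulate_reflectance(c(oxy = 0.2, cytc = 1), noise_sd = 0)
  An <- normalize_band(absorbance(cyt$sample, cyt$reference))
  pkc <- band_peaks(An, band = c(500, 600), min_prominence = 0.05)
  tallest <- pkc[which.max(pkc$value), ]
  expect_lt(abs(tallest$wavelength_nm - 550), 2.01)
  expect_error(simulate_reflectance(c(oxy = -1)), ">= 0")
})

test_that("cohort generation respects the spec and is stream-independent", {
  spec <- shrunk_spec()
  # zero SDs: all 9 measurement values equal the trajectory mean
  spec0 <- spec
  spec0$params$sd_between <- 0
  co <- generate_cohort(spec0, config = small_config(), seed = 3,
                        channels = 4L, rois = "LVA")
  mt <- co$measurement_truth
  one <- mt[mt$parameter == "tau1_ch4" & mt$group == "MI" & mt$week == 1, ]
  expect_equal(unique(one$true_value), 0.303)
  # group sizes honored
  expect_equal(length(unique(co$manifest$animal_id[co$manifest$group == "AMC"])),
               sum(spec0$group_sizes$AMC))
  # same seed: identical; changing one animal leaves others untouched
  co2 <- generate_cohort(spec0, config = small_config(), seed = 3,
                         channels = 4L, rois = "LVA")
  expect_identical(co$histograms, co2$histograms)
  spec_wider <- spec0
  spec_wider$group_sizes$MI <- c(3, 2)
  co3 <- generate_cohort(spec_wider, config = small_config(), seed = 3,
                         channels = 4L, rois = "LVA")
  shared <- intersect(names(co$histograms), names(co3$histograms))
  expect_gt(length(shared), 0)
  for (nm in shared)
    expect_identical(co$histograms[[nm]]$counts, co3$histograms[[nm]]$counts)
})

test_that("default trajectories encode the week-1 to week-16 infarct rise", {
  spec <- default_cohort_spec()
  p <- spec$params
  mi <- p[p$group == "MI" & p$roi == "LVA" & p$parameter == "tau1_ch4", ]
  expect_equal(mi$mean[mi$week == 1], 0.303)
  expect_equal(mi$mean[mi$week == 16], 0.566)
  expect_equal(mi$sd_between[mi$week == 1], 0.089)
  expect_equal(mi$sd_between[mi$week == 16], 0.057)
  expect_true(all(diff(mi$mean[order(mi$week)]) > 0))
  amc <- p[p$group == "AMC" & p$roi == "LVA" & p$parameter == "tau1_ch4", ]
  expect_true(all(amc$mean == 0.410))
  expect_equal(spec$group_sizes$AMC, c(3, 4, 4, 6))
  expect_equal(spec$group_sizes$MI, c(3, 3, 3, 6))
})

test_that("per-animal true values concentrate on the trajectory mean", {
  # 1000 animals (one week, one region, no histograms): the empirical mean
  # of the generated per-animal truths sits within 3 SE of the trajectory
  spec <- shrunk_spec(n = 500L, weeks = 16)
  co <- generate_cohort(spec, config = small_config(), seed = 6,
                        channels = integer(0), rois = "LVA")
  gt <- co$ground_truth
  for (param in c("tau1_ch4", "tau_ch1")) {
    row <- spec$params[spec$params$group == "MI" & spec$params$roi == "LVA" &
                         spec$params$parameter == param, ]
    vals <- gt$true_value[gt$group == "MI" & gt$parameter == param]
    expect_equal(length(vals), 500)
    se <- row$sd_between / sqrt(500)
    expect_lt(abs(mean(vals) - row$mean), 3 * se + 1e-3)
  }
})
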