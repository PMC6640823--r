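#' Simulation configuration
#'
#' Instrument constants for the synthetic-data generator, matching the study
#' setup: 20 MHz pulsed excitation (50 ns period), 1024 time bins of 48.8 ps,
#' ~200 ps reference-dye IRF measurements, and per-channel photon budgets
#' reflecting the low channel-1 signal (single-exponential policy) versus
#' channels 2-4.
#'
#' @param n_bins number of TCSPC time bins.
#' @param bin_width_ps bin width, ps.
#' @param rep_rate_mhz laser repetition rate, MHz.
#' @param total_counts named per-channel expected total photon counts.
#' @param irf_fwhm_ps FWHM of the Gaussian instrument pulse, ps.
#' @param irf_center_ns position of the excitation pulse inside the window,
#'   ns (must stay in the first quarter).
#' @param irf_reference_lifetime_ps lifetime of the reference dye used for
#'   IRF measurements, ps (0 = ideal instantaneous emitter).
#' @param irf_total_counts photon budget of an IRF measurement.
#' @param afterpulse_prob detector afterpulsing probability.
#' @param dark_offset dark/ambient background, counts per bin.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_bins = 1024L, bin_width_ps = 48.8, rep_rate_mhz = 20,
                       total_counts = c(ch1 = 5e3, ch2 = 5e4, ch3 = 5e4,
                                        ch4 = 5e4),
                       irf_fwhm_ps = 300, irf_center_ns = 5,
                       irf_reference_lifetime_ps = 200,
                       irf_total_counts = 1e5,
                       afterpulse_prob = 0.01, dark_offset = 0.2) {
  rep_period_ns <- 1000 / rep_rate_mhz
  if (n_bins * bin_width_ps / 1000 > rep_period_ns + bin_width_ps / 1000)
    stop("time window exceeds the repetition period", call. = FALSE)
  if (irf_center_ns > rep_period_ns / 4)
    stop("IRF pulse must sit in the first quarter of the window",
         call. = FALSE)
  structure(list(n_bins = as.integer(n_bins), bin_width_ps = bin_width_ps,
                 rep_rate_mhz = rep_rate_mhz, rep_period_ns = rep_period_ns,
                 total_counts = total_counts, irf_fwhm_ps = irf_fwhm_ps,
                 irf_center_ns = irf_center_ns,
                 irf_reference_lifetime_ps = irf_reference_lifetime_ps,
                 irf_total_counts = irf_total_counts,
                 afterpulse_prob = afterpulse_prob,
                 dark_offset = dark_offset),
            class = "sim_config")
}

# independent circular convolution used by the simulator: stats::convolve,
# orientation fixed so a delta kernel at bin 1 is the identity
sim_circular_conv <- function(x, kern) {
  n <- length(x)
  stats::convolve(x, c(kern[1L], rev(kern[-1L])), type = "circular")
}

#' Simulate an IRF measurement
#'
#' Emulates the reference-dye IRF measurement as a Gaussian instrument pulse
#' (FWHM `irf_fwhm_ps`) convolved with the dye's single-exponential decay
#' (`irf_reference_lifetime_ps`), plus the dark background, Poisson-sampled.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param channel detection channel recorded in the result.
#' @param noiseless return the expected (non-integer) curve instead of a
#'   Poisson draw.
#' @return an [instrument_response()].
#' @export
simulate_irf <- function(config = sim_config(), seed = 1L, channel = 1L,
                         noiseless = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dt <- config$bin_width_ps / 1000
  t <- (seq_len(config$n_bins) - 1L) * dt
  sigma <- config$irf_fwhm_ps / 1000 / (2 * sqrt(2 * log(2)))
  gauss <- stats::dnorm(t, mean = config$irf_center_ns, sd = sigma)
  tau_ref <- config$irf_reference_lifetime_ps / 1000
  if (tau_ref > 0) {
    expo <- exp(-t / tau_ref)
    shape <- sim_circular_conv(expo, gauss / sum(gauss))
  } else {
    shape <- gauss
  }
  shape <- pmax(shape, 0)
  shape <- shape / sum(shape)
  signal_total <- max(config$irf_total_counts -
                        config$n_bins * config$dark_offset, 1)
  expected <- shape * signal_total + config$dark_offset
  counts <- if (noiseless) expected else {
    set.seed(seed)
    stats::rpois(config$n_bins, expected)
  }
  instrument_response(
    counts, config$bin_width_ps, config$rep_period_ns, channel = channel,
    reference_lifetime_ps = config$irf_reference_lifetime_ps,
    meta = list(simulated = TRUE, seed = seed, noiseless = noiseless),
    check_integer = !noiseless)
}

#' Simulate a TCSPC decay measurement
#'
#' Forward model: the periodic multi-exponential decay (summed brute-force
#' over the preceding pulse train), convolved with the prepared IRF kernel,
#' plus the signal-proportional afterpulsing background and the dark offset,
#' scaled so the expected total equals the channel's photon budget, then
#' Poisson-sampled per bin. The forward model shares no code path with the
#' fitting module (pulse-train summation instead of the closed-form factor,
#' `stats::convolve` instead of the package FFT reconvolution), so
#' round-trip agreement cross-validates both implementations.
#'
#' @param true_params a [decay_params()] with the ground-truth components
#'   (amplitude scale is irrelevant; the curve is rescaled to the photon
#'   budget). `offset` is ignored in favor of `config$dark_offset`.
#' @param irf the [instrument_response()] to convolve with.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param channel detection channel (selects the photon budget).
#' @param total_counts override of the expected total counts.
#' @param noiseless return the expected curve instead of a Poisson draw.
#' @return a [decay_histogram()] with `meta$true_params` recording the truth.
#' @export
simulate_decay <- function(true_params, irf, config = sim_config(),
                           seed = 1L, channel = 4L, total_counts = NULL,
                           noiseless = FALSE) {
  stopifnot(inherits(true_params, "decay_params"),
            inherits(config, "sim_config"))
  n <- config$n_bins
  dt <- config$bin_width_ps / 1000
  t <- (seq_len(n) - 1L) * dt
  T_ns <- config$rep_period_ns
  # brute-force pile-up of preceding pulses (independent of the closed form)
  curve <- numeric(n)
  for (i in seq_along(true_params$alpha)) {
    tau <- true_params$tau_ns[i]
    K <- min(max(ceiling(35 * tau / T_ns), 1), 5000)
    comp <- numeric(n)
    for (k in 0:K) comp <- comp + exp(-(t + k * T_ns) / tau)
    curve <- curve + true_params$alpha[i] * comp
  }
  kern <- prepare_irf(irf)
  if (length(kern) != n)
    stop("IRF grid does not match the configuration", call. = FALSE)
  sig <- pmax(sim_circular_conv(curve, kern), 0)
  budget <- total_counts %||%
    config$total_counts[[paste0("ch", channel)]]
  if (is.null(budget)) stop("no photon budget for this channel", call. = FALSE)
  p_ap <- config$afterpulse_prob
  sig_total_target <- max(budget - n * config$dark_offset, 1) / (1 + p_ap)
  sig <- sig * sig_total_target / sum(sig)
  expected <- sig + p_ap * sum(sig) / n + config$dark_offset
  if (any(expected < 0)) stop("negative expected counts", call. = FALSE)
  counts <- if (noiseless) expected else {
    set.seed(seed)
    stats::rpois(n, expected)
  }
  decay_histogram(
    counts, config$bin_width_ps, config$rep_period_ns, channel = channel,
    meta = list(true_params = true_params, seed = seed,
                noiseless = noiseless, total_counts = budget),
    check_integer = !noiseless)
}

# stylized chromophore absorbance basis: Gaussian bands at the wavelengths
# of the oxyhemoglobin/oxymyoglobin double peak, reduced cytochrome c and
# deoxyhemoglobin features
chromophore_basis <- function(wl) {
  g <- function(mu, s) exp(-((wl - mu) / s)^2 / 2)
  list(oxy = g(542, 9) + 0.95 * g(577, 10),
       cytc = 0.6 * g(520, 8) + g(550, 8),
       deoxy = g(555, 14))
}

#' Simulate a diffuse-reflectance measurement
#'
#' Builds a ground-truth absorbance spectrum as a non-negative mixture of
#' stylized chromophore bands (oxyhemoglobin/oxymyoglobin double peak at
#' 542/577 nm, reduced cytochrome c at 520/550 nm, deoxyhemoglobin at
#' 555 nm), a smooth lamp reference, and the sample spectrum
#' `reference * 10^(-A_true)` with multiplicative noise.
#'
#' @param weights named non-negative mixture weights `oxy`, `cytc`, `deoxy`
#'   (missing entries are 0).
#' @param seed integer seed.
#' @param wavelength_nm wavelength grid, nm.
#' @param noise_sd multiplicative (log-normal) noise SD; 0 for noiseless.
#' @return list with `sample` and `reference` `optical_spectrum` objects;
#'   the ground-truth absorbance is stored in `sample$meta$A_true`.
#' @export
simulate_reflectance <- function(weights, seed = 1L,
                                 wavelength_nm = 450:650, noise_sd = 0.01) {
  w <- c(oxy = 0, cytc = 0, deoxy = 0)
  w[names(weights)] <- as.numeric(weights)
  if (any(w < 0)) stop("chromophore weights must be >= 0", call. = FALSE)
  basis <- chromophore_basis(wavelength_nm)
  A_true <- w[["oxy"]] * basis$oxy + w[["cytc"]] * basis$cytc +
    w[["deoxy"]] * basis$deoxy
  # smooth halogen-like lamp curve rising towards the red
  I0 <- 4000 * exp(-((wavelength_nm - 640) / 180)^2) + 300
  I <- I0 * 10^(-A_true)
  if (noise_sd > 0) {
    set.seed(seed)
    I <- I * exp(stats::rnorm(length(I), 0, noise_sd))
  }
  list(sample = optical_spectrum(wavelength_nm, I, kind = "raw",
                                 meta = list(A_true = A_true, seed = seed,
                                             weights = w)),
       reference = optical_spectrum(wavelength_nm, I0, kind = "reference"))
}

#' Solve a double-exponential construction from its mean lifetime
#'
#' Given the short lifetime, its intensity fraction and the target
#' intensity-weighted mean lifetime, solves the long lifetime and the
#' amplitude split, since \eqn{\tau_{mean} = f_1\tau_1 + f_2\tau_2} and
#' \eqn{\alpha_1/\alpha_2 = (f_1/f_2)(\tau_2/\tau_1)}.
#'
#' @param tau1_ns short-component lifetime, ns.
#' @param f1 short-component intensity fraction, in (0, 1).
#' @param tau_mean_ns target intensity-weighted mean lifetime, ns.
#' @return a [decay_params()] with unit total amplitude.
#' @export
solve_double_exp <- function(tau1_ns, f1, tau_mean_ns) {
  if (f1 <= 0 || f1 >= 1) stop("`f1` must lie in (0, 1)", call. = FALSE)
  tau2 <- (tau_mean_ns - f1 * tau1_ns) / (1 - f1)
  if (tau2 <= tau1_ns)
    stop("target mean lifetime is incompatible with tau1/f1", call. = FALSE)
  r <- (f1 / (1 - f1)) * (tau2 / tau1_ns)  # alpha1/alpha2
  a1 <- r / (1 + r)
  decay_params(alpha = c(a1, 1 - a1), tau_ns = c(tau1_ns, tau2))
}

#' Lifetime-recovery experiment
#'
#' Simulates `n_rep` Poisson realizations of a decay with fixed ground-truth
#' parameters and refits each by IRF reconvolution, returning the fitted
#' parameters per replicate. This is the package's standard protocol for
#' validating parameter recovery against known truths.
#'
#' @param true_params ground-truth [decay_params()].
#' @param n_components components to fit (1 or 2).
#' @param n_rep number of Poisson replicates.
#' @param seed base seed; replicate i uses `substream(seed, i)`.
#' @param config a [sim_config()].
#' @param irf IRF used for simulation and fitting; default is the noiseless
#'   Gaussian-pulse IRF of the configuration.
#' @param channel channel (photon budget and policy metadata).
#' @param options [fit_options()] passed to the fitter.
#' @return data.frame with one row per replicate: fitted `tau1`, `tau2`,
#'   `alpha1`, `alpha2`, `tau_mean`, `chi2_reduced`, `converged`.
#' @export
recover_lifetimes <- function(true_params, n_components = 2L, n_rep = 20L,
                              seed = 1L, config = sim_config(), irf = NULL,
                              channel = 4L, options = fit_options()) {
  if (is.null(irf)) {
    irf_cfg <- config
    irf_cfg$irf_reference_lifetime_ps <- 0
    irf_cfg$dark_offset <- 0
    irf <- simulate_irf(irf_cfg, noiseless = TRUE, channel = channel)
  }
  rows <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    h <- simulate_decay(true_params, irf, config,
                        seed = substream(seed, i), channel = channel)
    fit <- fit_decay(h, irf, n_components = n_components, options = options)
    k <- length(fit$params$tau_ns)
    rows[[i]] <- data.frame(
      rep = i,
      tau1 = fit$params$tau_ns[1L],
      tau2 = if (k >= 2L) fit$params$tau_ns[2L] else NA_real_,
      alpha1 = fit$params$alpha[1L],
      alpha2 = if (k >= 2L) fit$params$alpha[2L] else NA_real_,
      tau_mean = fit$tau_mean_ns,
      chi2_reduced = fit$chi2_reduced,
      converged = fit$converged)
  }
  do.call(rbind, rows)
}
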