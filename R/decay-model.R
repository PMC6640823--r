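#' Multi-exponential decay model parameters
#'
#' Parameters of the fluorescence decay model
#' \deqn{I(t) = \sum_i \alpha_i e^{-t/\tau_i} + C}
#' together with the detector afterpulsing probability and a signed sub-bin
#' timing shift of the IRF. Components are stored sorted by lifetime
#' ascending, so `tau[1]` is always the short ("fast") component.
#'
#' @param alpha non-negative pre-exponential amplitudes (counts/bin scale).
#' @param tau_ns strictly positive lifetimes, ns.
#' @param offset constant background offset C, counts per bin, >= 0.
#' @param afterpulse_prob detector afterpulsing probability, in [0, 0.2];
#'   modeled as a time-uniform background proportional to the detected
#'   signal.
#' @param irf_shift_ps signed sub-bin shift of the IRF, ps.
#' @return an object of class `decay_params`.
#' @export
decay_params <- function(alpha, tau_ns, offset = 0, afterpulse_prob = 0.01,
                         irf_shift_ps = 0) {
  alpha <- as.numeric(alpha); tau_ns <- as.numeric(tau_ns)
  if (length(alpha) != length(tau_ns))
    stop("`alpha` and `tau_ns` must have the same length", call. = FALSE)
  if (length(alpha) < 1L || length(alpha) > 3L)
    stop("between 1 and 3 decay components are supported", call. = FALSE)
  if (any(!is.finite(tau_ns)) || any(tau_ns <= 0))
    stop("lifetimes must be strictly positive", call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("amplitudes must be non-negative", call. = FALSE)
  if (offset < 0) stop("`offset` must be >= 0", call. = FALSE)
  if (afterpulse_prob < 0 || afterpulse_prob > 0.2)
    stop("`afterpulse_prob` must lie in [0, 0.2]", call. = FALSE)
  ord <- order(tau_ns)
  structure(list(alpha = alpha[ord], tau_ns = tau_ns[ord],
                 offset = as.numeric(offset),
                 afterpulse_prob = as.numeric(afterpulse_prob),
                 irf_shift_ps = as.numeric(irf_shift_ps)),
            class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  comp <- paste(sprintf("alpha=%.4g tau=%.4g ns", x$alpha, x$tau_ns),
                collapse = "; ")
  cat(sprintf("<decay_params> %s | C=%.4g, p_ap=%.3g, shift=%.3g ps\n",
              comp, x$offset, x$afterpulse_prob, x$irf_shift_ps))
  invisible(x)
}

#' Incomplete-decay (periodic pile-up) correction factor
#'
#' At high repetition rate the fluorescence excited by all preceding pulses
#' piles into the current period. For a single-exponential component the
#' steady-state sum over the pulse train is a geometric series,
#' \deqn{\sum_{k \ge 0} e^{-kT/\tau} = \frac{1}{1 - e^{-T/\tau}},}
#' so multiplying \eqn{e^{-t/\tau}} by this factor gives the periodic
#' steady-state decay on \eqn{[0, T)}.
#'
#' @param tau_ns component lifetime, ns.
#' @param rep_period_ns repetition period T, ns.
#' @return the dimensionless correction factor, >= 1.
#' @export
periodic_decay_factor <- function(tau_ns, rep_period_ns) {
  if (any(!is.finite(tau_ns)) || any(tau_ns <= 0))
    stop("`tau_ns` must be strictly positive", call. = FALSE)
  if (any(!is.finite(rep_period_ns)) || any(rep_period_ns <= 0))
    stop("`rep_period_ns` must be strictly positive", call. = FALSE)
  1 / (1 - exp(-rep_period_ns / tau_ns))
}

#' Evaluate the periodic multi-exponential decay curve (pre-IRF)
#'
#' Per bin time t: \eqn{\sum_i \alpha_i e^{-t/\tau_i} / (1 - e^{-T/\tau_i})}.
#' The constant offset and the afterpulse level are added only after IRF
#' convolution (see [fit_decay()]), since they are detector-side terms.
#'
#' @param params a [decay_params()] object.
#' @param grid_ns bin times (ns) spanning `[0, T)`.
#' @param rep_period_ns repetition period T, ns.
#' @return expected counts per bin (same length as `grid_ns`).
#' @export
model_curve <- function(params, grid_ns, rep_period_ns) {
  stopifnot(inherits(params, "decay_params"))
  if (length(params$alpha) == 0L) stop("empty component list", call. = FALSE)
  out <- numeric(length(grid_ns))
  for (i in seq_along(params$alpha)) {
    f <- periodic_decay_factor(params$tau_ns[i], rep_period_ns)
    out <- out + params$alpha[i] * f * exp(-grid_ns / params$tau_ns[i])
  }
  out
}

# shift a periodic kernel by a (possibly fractional) number of bins,
# using circular roll + linear interpolation for the sub-bin part
shift_kernel <- function(kern, shift_bins) {
  i <- floor(shift_bins)
  f <- shift_bins - i
  if (f == 0) return(circ_shift(kern, i))
  (1 - f) * circ_shift(kern, i) + f * circ_shift(kern, i + 1)
}

#' Circular IRF reconvolution
#'
#' Convolves a model decay curve with the measured instrument response over
#' one repetition period. The convolution is circular, consistent with the
#' steady-state periodic-excitation picture used for the incomplete-decay
#' correction. An optional signed `irf_shift_ps` is applied to the kernel as
#' a sub-bin linear-interpolation shift before convolving.
#'
#' @param curve expected counts per bin (pre-IRF), from [model_curve()].
#' @param irf an [instrument_response()] on the identical grid, or a numeric
#'   kernel (background-subtracted and area-normalized, see [prepare_irf()]).
#' @param irf_shift_ps signed timing shift of the IRF, ps.
#' @param bin_width_ps bin width, ps; required when `irf` is a bare numeric
#'   kernel and `irf_shift_ps != 0`.
#' @return convolved counts per bin.
#' @export
convolve_irf <- function(curve, irf, irf_shift_ps = 0, bin_width_ps = NULL) {
  if (inherits(irf, "decay_histogram")) {
    bin_width_ps <- irf$bin_width_ps
    kern <- prepare_irf(irf)
  } else {
    kern <- as.numeric(irf)
  }
  if (length(kern) != length(curve))
    stop("curve and IRF must be on identical grids", call. = FALSE)
  if (irf_shift_ps != 0) {
    if (is.null(bin_width_ps))
      stop("`bin_width_ps` is required to apply an IRF shift", call. = FALSE)
    kern <- shift_kernel(kern, irf_shift_ps / bin_width_ps)
  }
  n <- length(curve)
  Re(stats::fft(stats::fft(curve) * stats::fft(kern), inverse = TRUE)) / n
}

#' Intensity-weighted mean fluorescence lifetime
#'
#' \deqn{\tau_{mean} = \frac{\sum_i \alpha_i \tau_i^2}{\sum_i \alpha_i \tau_i}}
#' Each component is weighted by its integrated intensity \eqn{\alpha_i\tau_i}.
#' For a single component this reduces to \eqn{\tau_1}.
#'
#' @param params a [decay_params()] object, or a numeric vector of amplitudes
#'   when `tau_ns` is supplied.
#' @param tau_ns lifetimes (ns) when `params` is an amplitude vector.
#' @return mean lifetime, ns.
#' @export
mean_lifetime <- function(params, tau_ns = NULL) {
  if (inherits(params, "decay_params")) {
    a <- params$alpha; tau <- params$tau_ns
  } else {
    a <- as.numeric(params); tau <- as.numeric(tau_ns)
  }
  denom <- sum(a * tau)
  if (denom <= 0) stop("total intensity is zero", call. = FALSE)
  sum(a * tau^2) / denom
}

#' Per-component intensity fractions
#'
#' Fraction of the modeled signal carried by each component. Over one full
#' period the integrated intensity of a periodic component is exactly
#' \eqn{\alpha_i\tau_i}, so the fractions are
#' \eqn{\alpha_i\tau_i / \sum_j \alpha_j\tau_j}.
#'
#' @inheritParams mean_lifetime
#' @return fractions summing to 1.
#' @export
intensity_fractions <- function(params, tau_ns = NULL) {
  if (inherits(params, "decay_params")) {
    a <- params$alpha; tau <- params$tau_ns
  } else {
    a <- as.numeric(params); tau <- as.numeric(tau_ns)
  }
  w <- a * tau
  if (sum(w) <= 0) stop("total intensity is zero", call. = FALSE)
  w / sum(w)
}

#' Reduced chi-squared goodness of fit
#'
#' Neyman-weighted: \eqn{\chi^2_r = \frac{1}{N - k}\sum_j
#' \frac{(O_j - E_j)^2}{\max(O_j, 1)}} with N bins and k free parameters.
#'
#' @param observed observed counts per bin.
#' @param fitted fitted (expected) counts per bin.
#' @param n_free number of free fit parameters, `< length(observed)`.
#' @return reduced chi-squared.
#' @export
reduced_chi2 <- function(observed, fitted, n_free) {
  if (length(observed) != length(fitted))
    stop("`observed` and `fitted` have different lengths", call. = FALSE)
  if (n_free >= length(observed))
    stop("`n_free` must be smaller than the number of bins", call. = FALSE)
  sum((observed - fitted)^2 / pmax(observed, 1)) /
    (length(observed) - n_free)
}
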