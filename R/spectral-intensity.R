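#' Background-corrected total channel intensity
#'
#' Integrates a decay histogram into a total intensity I_n, subtracting the
#' (fitted) constant offset per bin. Clipped at zero.
#'
#' @param hist a [decay_histogram()].
#' @param offset_C background offset in counts per bin (>= 0); typically the
#'   fitted C of the decay model, or 0 when no fit exists.
#' @return total background-corrected counts.
#' @export
integrate_histogram <- function(hist, offset_C = 0) {
  stopifnot(inherits(hist, "decay_histogram"))
  if (offset_C < 0) stop("`offset_C` must be >= 0", call. = FALSE)
  max(sum(hist$counts) - offset_C * hist$n_bins, 0)
}

#' Normalized spectral-channel intensity fractions
#'
#' Fraction of the total autofluorescence signal detected under 372 nm
#' excitation in each of channels 1-3:
#' \deqn{F_n = I_n / (I_1 + I_2 + I_3)}
#' Channel 4 (438 nm excitation) is excluded because it is acquired with a
#' separate laser and is sensitive to day-to-day coupling and power
#' differences between the two sources.
#'
#' @param I1,I2,I3 background-corrected channel intensities (counts).
#' @return named vector `c(F1, F2, F3)` summing to 1.
#' @export
normalized_fractions <- function(I1, I2, I3) {
  I <- c(I1, I2, I3)
  if (length(I) != 3L || any(!is.finite(I)) || any(I < 0))
    stop("intensities must be three non-negative finite numbers",
         call. = FALSE)
  tot <- sum(I)
  if (tot <= 0)
    stop("total intensity is zero: measurement flagged unusable",
         call. = FALSE)
  stats::setNames(I / tot, c("F1", "F2", "F3"))
}
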