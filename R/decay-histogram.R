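#' Construct a TCSPC decay histogram
#'
#' A decay histogram holds the binned photon arrival times for one measurement
#' in one spectral detection channel, together with the timing metadata needed
#' for reconvolution fitting: the bin width, the laser repetition period
#' (50 ns at 20 MHz) and the channel number.
#'
#' @param counts non-negative photon counts per time bin.
#' @param bin_width_ps time bin width in picoseconds.
#' @param rep_period_ns laser repetition period in nanoseconds (1/repetition
#'   rate; 50 ns at 20 MHz).
#' @param channel detection channel, 1-4 (1: 410+/-10 nm, 2: 455+/-25 nm,
#'   3: 525+/-25 nm under 372 nm excitation, 4: 525+/-25 nm under 438 nm
#'   excitation).
#' @param meta optional named list of provenance (animal, ROI, position,
#'   repeat, excitation wavelength, simulation ground truth, ...).
#' @param check_integer require integral counts (disable for noiseless
#'   simulated expectation curves).
#' @return an object of class `decay_histogram`.
#' @export
decay_histogram <- function(counts, bin_width_ps, rep_period_ns, channel,
                            meta = list(), check_integer = TRUE) {
  counts <- as.numeric(counts)
  stop_if_not_scalar_pos(bin_width_ps, "bin_width_ps")
  stop_if_not_scalar_pos(rep_period_ns, "rep_period_ns")
  if (length(counts) < 64L)
    stop("a decay histogram needs at least 64 bins", call. = FALSE)
  if (anyNA(counts) || any(counts < 0)) {
    bad <- which(is.na(counts) | counts < 0)[1L]
    stop(sprintf("negative or missing count at bin %d", bad), call. = FALSE)
  }
  if (check_integer && any(abs(counts - round(counts)) > 1e-9)) {
    bad <- which(abs(counts - round(counts)) > 1e-9)[1L]
    stop(sprintf("non-integer count at bin %d", bad), call. = FALSE)
  }
  n <- length(counts)
  # the histogram window must fit inside one repetition period (+1 bin slack)
  if (n * bin_width_ps / 1000 > rep_period_ns + bin_width_ps / 1000 + 1e-9)
    stop("histogram window exceeds the repetition period", call. = FALSE)
  channel <- as.integer(channel)
  if (!channel %in% 1:4)
    stop("`channel` must be one of 1, 2, 3, 4", call. = FALSE)
  structure(
    list(counts = counts, bin_width_ps = as.numeric(bin_width_ps),
         n_bins = n, rep_period_ns = as.numeric(rep_period_ns),
         channel = channel, meta = meta),
    class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf(
    "<decay_histogram> channel %d: %d bins x %.4g ps (period %.4g ns), %s counts\n",
    x$channel, x$n_bins, x$bin_width_ps, x$rep_period_ns,
    format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Time grid of a histogram
#'
#' Bin left-edge times in nanoseconds, starting at zero.
#'
#' @param hist a `decay_histogram` or `instrument_response`.
#' @return numeric vector of times (ns).
#' @export
time_grid <- function(hist) {
  (seq_len(hist$n_bins) - 1L) * hist$bin_width_ps / 1000
}

#' Construct an instrument response function measurement
#'
#' The IRF for each channel is measured with a short-lifetime (~200 ps)
#' reference dye; the recorded histogram (on the same time grid as the tissue
#' decays) is used directly as the reconvolution kernel after background
#' subtraction and area normalization (see [prepare_irf()]).
#'
#' @param counts counts per bin, same grid as the decay histograms.
#' @inheritParams decay_histogram
#' @param reference_lifetime_ps nominal lifetime of the reference dye (ps).
#' @return an object of class `instrument_response`.
#' @export
instrument_response <- function(counts, bin_width_ps, rep_period_ns,
                                channel = 1L, reference_lifetime_ps = 200,
                                meta = list(), check_integer = TRUE) {
  h <- decay_histogram(counts, bin_width_ps, rep_period_ns, channel,
                       meta = meta, check_integer = check_integer)
  if (reference_lifetime_ps < 0)
    stop("`reference_lifetime_ps` must be >= 0", call. = FALSE)
  h$reference_lifetime_ps <- as.numeric(reference_lifetime_ps)
  class(h) <- c("instrument_response", "decay_histogram")
  h
}

#' Prepare an IRF measurement as a reconvolution kernel
#'
#' Subtracts the background level estimated from the pre-rise region (mean of
#' the first `pre_rise_frac` of bins), clips negatives, and normalizes the
#' result to unit area.
#'
#' @param irf an `instrument_response`, or a numeric vector already on the
#'   decay grid.
#' @param pre_rise_frac fraction of leading bins used for the background
#'   estimate (default 0.05).
#' @return numeric kernel summing to 1.
#' @export
prepare_irf <- function(irf, pre_rise_frac = 0.05) {
  counts <- if (inherits(irf, "decay_histogram")) irf$counts else as.numeric(irf)
  n <- length(counts)
  n_pre <- max(1L, floor(n * pre_rise_frac))
  bg <- mean(counts[seq_len(n_pre)])
  w <- pmax(counts - bg, 0)
  tot <- sum(w)
  if (tot <= 0)
    stop("IRF has no signal above the estimated background", call. = FALSE)
  w / tot
}

# ---- fixture dialect ("tcspc-csv") ------------------------------------------

#' Read a TCSPC histogram fixture
#'
#' The plain-text dialect has `# key=value` header lines (`bin_width_ps`,
#' `rep_period_ns`, `channel`, and for IRFs `reference_lifetime_ps`; any
#' other keys are kept as metadata), then a `bin_index,counts` CSV body.
#' A `.json` envelope with the same fields and a `meta` object is also
#' accepted. CRLF and LF line endings parse identically.
#'
#' @param path file to read.
#' @param irf if `TRUE`, return an [instrument_response()].
#' @return a `decay_histogram` or `instrument_response`.
#' @export
read_histogram <- function(path, irf = grepl("irf", basename(path))) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    hdr <- x[setdiff(names(x), c("counts", "meta"))]
    counts <- as.numeric(x$counts)
    meta <- as.list(x$meta %||% list())
  } else {
    lines <- gsub("\r$", "", readLines(path, warn = FALSE))
    hdr_lines <- grep("^#", lines, value = TRUE)
    hdr <- list()
    for (l in hdr_lines) {
      kv <- strsplit(sub("^#\\s*", "", l), "=", fixed = TRUE)[[1L]]
      if (length(kv) == 2L) hdr[[trimws(kv[1L])]] <- trimws(kv[2L])
    }
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    df <- utils::read.csv(text = paste(body, collapse = "\n"))
    if (!all(c("bin_index", "counts") %in% names(df)))
      stop("histogram body must have `bin_index,counts` columns", call. = FALSE)
    df <- df[order(df$bin_index), , drop = FALSE]
    counts <- as.numeric(df$counts)
    known <- c("bin_width_ps", "rep_period_ns", "channel",
               "reference_lifetime_ps")
    meta <- hdr[setdiff(names(hdr), known)]
  }
  for (key in c("bin_width_ps", "rep_period_ns", "channel")) {
    if (is.null(hdr[[key]]))
      stop(sprintf("histogram header is missing required key `%s`", key),
           call. = FALSE)
  }
  if (any(counts < 0)) {
    stop(sprintf("negative count at bin %d", which(counts < 0)[1L] - 1L),
         call. = FALSE)
  }
  if (irf) {
    instrument_response(
      counts, as.numeric(hdr$bin_width_ps), as.numeric(hdr$rep_period_ns),
      as.integer(hdr$channel),
      reference_lifetime_ps = as.numeric(hdr$reference_lifetime_ps %||% 200),
      meta = meta)
  } else {
    decay_histogram(counts, as.numeric(hdr$bin_width_ps),
                    as.numeric(hdr$rep_period_ns), as.integer(hdr$channel),
                    meta = meta)
  }
}

#' Write a TCSPC histogram fixture
#'
#' @param hist a `decay_histogram` or `instrument_response`.
#' @param path destination file (`.csv` dialect).
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  hdr <- c(sprintf("# bin_width_ps=%.10g", hist$bin_width_ps),
           sprintf("# rep_period_ns=%.10g", hist$rep_period_ns),
           sprintf("# channel=%d", hist$channel))
  if (inherits(hist, "instrument_response"))
    hdr <- c(hdr, sprintf("# reference_lifetime_ps=%.10g",
                          hist$reference_lifetime_ps))
  scalar_meta <- Filter(function(v) is.atomic(v) && length(v) == 1L, hist$meta)
  for (k in names(scalar_meta))
    hdr <- c(hdr, sprintf("# %s=%s", k, format(scalar_meta[[k]])))
  body <- sprintf("%d,%.10g", seq_along(hist$counts) - 1L, hist$counts)
  writeLines(c(hdr, "bin_index,counts", body), path)
  invisible(path)
}
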