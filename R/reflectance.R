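#' Construct a wavelength-indexed spectrum
#'
#' @param wavelength_nm strictly increasing wavelengths, nm.
#' @param value intensities (arbitrary units, >= 0 for raw/reference kinds)
#'   or absorbance values; `NA` marks bins flagged missing.
#' @param kind one of `"raw"`, `"reference"`, `"absorbance"`,
#'   `"normalized_absorbance"`.
#' @param meta optional named list of provenance.
#' @return an object of class `optical_spectrum`.
#' @export
optical_spectrum <- function(wavelength_nm, value,
                             kind = c("raw", "reference", "absorbance",
                                      "normalized_absorbance"),
                             meta = list()) {
  kind <- match.arg(kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value))
    stop("wavelength and value arrays differ in length", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (kind %in% c("raw", "reference") && any(value < 0, na.rm = TRUE))
    stop("raw/reference intensities must be non-negative", call. = FALSE)
  structure(list(wavelength_nm = wavelength_nm, value = value, kind = kind,
                 meta = meta),
            class = "optical_spectrum")
}

#' @export
print.optical_spectrum <- function(x, ...) {
  cat(sprintf("<optical_spectrum> kind=%s, %d points, %.0f-%.0f nm\n",
              x$kind, length(x$value), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  invisible(x)
}

#' Tissue absorbance from a diffuse-reflectance measurement
#'
#' Calibrates the measured reflected intensity against the white-reference
#' lamp spectrum and computes
#' \deqn{A(\lambda) = -\log_{10}\!\left(\frac{I(\lambda)}{I_0(\lambda)}\right).}
#' The reference is linearly interpolated onto the sample grid when the
#' grids differ. Non-positive sample bins are flagged `NA` (missing), never
#' fabricated; a non-positive reference value anywhere used is an error.
#'
#' @param sample measured tissue spectrum (`kind = "raw"`).
#' @param reference white-reference lamp spectrum (`kind = "reference"` or
#'   `"raw"`), covering the sample's wavelength range.
#' @return an `optical_spectrum` of kind `"absorbance"`.
#' @export
absorbance <- function(sample, reference) {
  stopifnot(inherits(sample, "optical_spectrum"),
            inherits(reference, "optical_spectrum"))
  if (min(sample$wavelength_nm) < min(reference$wavelength_nm) - 1e-9 ||
      max(sample$wavelength_nm) > max(reference$wavelength_nm) + 1e-9)
    stop("reference spectrum does not cover the sample wavelength range",
         call. = FALSE)
  I0 <- stats::approx(reference$wavelength_nm, reference$value,
                      xout = sample$wavelength_nm, rule = 2)$y
  if (any(!is.finite(I0)) || any(I0 <= 0))
    stop("non-positive reference intensity in the sample range",
         call. = FALSE)
  I <- sample$value
  A <- rep(NA_real_, length(I))
  ok <- is.finite(I) & I > 0
  A[ok] <- -log10(I[ok] / I0[ok])
  optical_spectrum(sample$wavelength_nm, A, kind = "absorbance",
                   meta = sample$meta)
}

#' Normalize an absorbance spectrum to its in-band maximum
#'
#' Divides the whole spectrum by its maximum inside `band` (default
#' 500-600 nm, the hemoglobin/cytochrome window), so the in-band maximum of
#' the output is exactly 1. Idempotent and invariant to overall scaling.
#'
#' @param A an absorbance `optical_spectrum`.
#' @param band numeric length-2 wavelength interval, nm.
#' @return an `optical_spectrum` of kind `"normalized_absorbance"`.
#' @export
normalize_band <- function(A, band = c(500, 600)) {
  stopifnot(inherits(A, "optical_spectrum"))
  sel <- A$wavelength_nm >= band[1L] & A$wavelength_nm <= band[2L]
  if (!any(sel)) stop("normalization band contains no points", call. = FALSE)
  m <- max(A$value[sel], na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("in-band maximum is not positive", call. = FALSE)
  optical_spectrum(A$wavelength_nm, A$value / m,
                   kind = "normalized_absorbance", meta = A$meta)
}

#' Locate absorbance peaks within a band
#'
#' Local maxima by 3-point comparison, kept when their prominence (peak
#' height above the higher of the bounding minima towards the nearest
#' higher ground on each side) is at least `min_prominence` times the
#' in-band value range. Returned sorted by wavelength. An empty result is
#' valid (e.g. a monotone spectrum).
#'
#' @param A an `optical_spectrum`.
#' @param band numeric length-2 wavelength interval, nm (>= 5 points).
#' @param min_prominence prominence threshold as a fraction of the in-band
#'   range.
#' @return data.frame with columns `wavelength_nm`, `value`.
#' @export
band_peaks <- function(A, band = c(500, 600), min_prominence = 0.05) {
  stopifnot(inherits(A, "optical_spectrum"))
  sel <- which(A$wavelength_nm >= band[1L] & A$wavelength_nm <= band[2L])
  if (length(sel) < 5L)
    stop("band must contain at least 5 points", call. = FALSE)
  v <- A$value[sel]
  wl <- A$wavelength_nm[sel]
  if (anyNA(v)) { keep <- !is.na(v); v <- v[keep]; wl <- wl[keep] }
  n <- length(v)
  if (n < 5L) stop("band must contain at least 5 valid points", call. = FALSE)
  rng <- diff(range(v))
  if (rng <= 0) return(data.frame(wavelength_nm = numeric(0),
                                  value = numeric(0)))
  is_max <- which(v[2:(n - 1L)] > v[1:(n - 2L)] &
                    v[2:(n - 1L)] > v[3:n]) + 1L
  out_wl <- numeric(0); out_v <- numeric(0)
  for (i in is_max) {
    # walk outwards to the nearest higher point (or band edge) on each side,
    # taking the minimum along the way; prominence = peak - higher of the two
    left_min <- v[i]
    j <- i
    while (j > 1L && v[j - 1L] <= v[i]) { j <- j - 1L; left_min <- min(left_min, v[j]) }
    right_min <- v[i]
    j <- i
    while (j < n && v[j + 1L] <= v[i]) { j <- j + 1L; right_min <- min(right_min, v[j]) }
    prom <- v[i] - max(left_min, right_min)
    if (prom >= min_prominence * rng) {
      out_wl <- c(out_wl, wl[i]); out_v <- c(out_v, v[i])
    }
  }
  ord <- order(out_wl)
  data.frame(wavelength_nm = out_wl[ord], value = out_v[ord])
}

# ---- spectrum fixture dialect ----------------------------------------------

#' Read a two-column spectrum fixture
#'
#' Dialect: optional `# kind=...` and other `# key=value` header lines, then
#' a `wavelength_nm,value` CSV body. CRLF and LF parse identically.
#'
#' @param path file to read.
#' @return an `optical_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  hdr_lines <- grep("^#", lines, value = TRUE)
  hdr <- list()
  for (l in hdr_lines) {
    kv <- strsplit(sub("^#\\s*", "", l), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) hdr[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop("spectrum body must have `wavelength_nm,value` columns",
         call. = FALSE)
  optical_spectrum(df$wavelength_nm, df$value,
                   kind = hdr$kind %||% "raw",
                   meta = hdr[setdiff(names(hdr), "kind")])
}

#' Write a two-column spectrum fixture
#'
#' @param spec an `optical_spectrum`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  hdr <- sprintf("# kind=%s", spec$kind)
  scalar_meta <- Filter(function(v) is.atomic(v) && length(v) == 1L, spec$meta)
  for (k in names(scalar_meta))
    hdr <- c(hdr, sprintf("# %s=%s", k, format(scalar_meta[[k]])))
  body <- sprintf("%.10g,%.10g", spec$wavelength_nm, spec$value)
  writeLines(c(hdr, "wavelength_nm,value", body), path)
  invisible(path)
}
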