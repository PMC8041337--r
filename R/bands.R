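#' Frequency band
#'
#' @param name Band label.
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @return An object of class `frequency_band`.
#' @export
frequency_band <- function(name, lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi <= lo)
    stop("frequency band requires 0 < lo < hi")
  structure(list(name = as.character(name), lo = lo, hi = hi),
            class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %s: %g-%g Hz\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Canonical analysis bands
#'
#' The three bands used throughout: delta/theta (2-8 Hz), low beta
#' (13-22 Hz) and high beta (23-30 Hz). Band averaging is inclusive at both
#' edges, so with 1 Hz bins the 22 Hz bin is assigned to low beta and high
#' beta starts at 23 Hz; this keeps the two beta bands disjoint on integer
#' grids.
#'
#' @return Named list of `frequency_band` objects.
#' @export
canonical_bands <- function() {
  list(
    delta_theta = frequency_band("delta_theta", 2, 8),
    low_beta    = frequency_band("low_beta", 13, 22),
    high_beta   = frequency_band("high_beta", 23, 30)
  )
}

#' Average a spectrum over a band
#'
#' Arithmetic mean over frequency bins with `lo <= f <= hi` (both edges
#' inclusive).
#'
#' @param spectrum Numeric vector of spectral values; if `freqs` is missing
#'   its `"freqs"` attribute is used.
#' @param band A `frequency_band`.
#' @param freqs Frequency axis in Hz matching `spectrum`.
#' @return Scalar band mean.
#' @export
band_average <- function(spectrum, band, freqs = attr(spectrum, "freqs")) {
  if (is.null(freqs)) stop("band_average needs a frequency axis")
  if (length(freqs) != length(spectrum))
    stop("spectrum and freqs lengths differ")
  sel <- freqs >= band$lo & freqs <= band$hi
  if (!any(sel)) stop("no frequency bins inside band ", band$name,
                      " [", band$lo, ", ", band$hi, "] Hz")
  mean(spectrum[sel])
}
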