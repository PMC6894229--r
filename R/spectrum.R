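#' Construct a 1D NMR spectrum
#'
#' A spectrum is a chemical-shift axis plus a same-length intensity vector,
#' the unit that all preprocessing steps transform.  The axis must be
#' strictly monotone (either direction); intensities may be any finite
#' real values.
#'
#' @param ppm Numeric chemical-shift axis (ppm), strictly monotone,
#'   length >= 2.
#' @param intensity Numeric intensity vector of the same length.
#' @param sample_id Character identifier for the sample.
#' @return An object of class `nmr_spectrum`: a list with elements `ppm`,
#'   `intensity` and `sample_id`.
#' @export
nmr_spectrum <- function(ppm, intensity, sample_id = "sample") {
  if (length(ppm) < 2) stop("spectrum needs at least 2 points")
  if (length(ppm) != length(intensity)) {
    stop("ppm and intensity must have equal length")
  }
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotone")
  structure(
    list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
         sample_id = as.character(sample_id)),
    class = "nmr_spectrum"
  )
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s: %d points, %.3f to %.3f ppm\n",
              x$sample_id, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

# trapezoid integral over a possibly gapped axis: spacings larger than
# `gap_factor` times the median spacing contribute no area
.trapz_gapped <- function(ppm, intensity, gap_factor = 1.5) {
  o <- order(ppm)
  x <- ppm[o]; y <- intensity[o]
  dx <- diff(x)
  med <- stats::median(dx)
  keep <- dx <= gap_factor * med
  sum(dx[keep] * (y[-length(y)][keep] + y[-1][keep]) / 2)
}
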