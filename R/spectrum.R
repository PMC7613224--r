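#' Construct a 1D NMR spectrum
#'
#' A spectrum is a chemical-shift axis (ppm) paired with an intensity trace.
#' The axis may be stored ascending or descending (NMR display convention is
#' descending); all package operations accept either orientation.
#'
#' @param ppm Numeric vector of chemical shifts, strictly monotone.
#' @param intensity Numeric vector of intensities, same length as `ppm`.
#' @param sample_id Character scalar identifying the sample.
#' @param meta Optional named list of metadata (e.g. applied referencing
#'   shift).
#' @return An object of class `nmr_spectrum`.
#' @export
new_spectrum <- function(ppm, intensity, sample_id = "sample", meta = list()) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  stop_if(length(ppm) != length(intensity),
          "ppm and intensity lengths differ (%d vs %d)",
          length(ppm), length(intensity))
  stop_if(length(ppm) < 2L, "a spectrum needs at least 2 points")
  d <- diff(ppm)
  stop_if(!(all(d > 0) || all(d < 0)), "ppm axis must be strictly monotone")
  stop_if(any(!is.finite(intensity)), "intensities must be finite")
  structure(
    list(ppm = ppm, intensity = intensity,
         sample_id = as.character(sample_id), meta = meta),
    class = "nmr_spectrum"
  )
}

# Return a copy with the ppm axis ascending.
ascending <- function(s) {
  if (s$ppm[1] > s$ppm[2]) {
    s$ppm <- rev(s$ppm)
    s$intensity <- rev(s$intensity)
  }
  s
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s: %d points, %.3f-%.3f ppm\n",
              x$sample_id, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Default chemical-shift axis
#'
#' @param n_points Number of points (default 32768).
#' @param from,to Axis limits in ppm.
#' @param descending Store high-to-low ppm (NMR display convention)?
#' @return Numeric ppm vector.
#' @export
default_ppm_axis <- function(n_points = 32768L, from = 0, to = 10,
                             descending = TRUE) {
  ax <- seq(from, to, length.out = n_points)
  if (descending) rev(ax) else ax
}
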