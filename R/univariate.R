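#' Build resonance definitions from a peak library
#'
#' One definition per metabolite: ppm intervals of half-width `pad` around
#' each library position (clipped to the bucketed region). Definitions of
#' overlapping resonances may share buckets; overlaps are permitted.
#'
#' @param library Peak library from [build_peak_library()].
#' @param pad Half-width (ppm) of the interval around each position.
#' @param region Bucketed region used for clipping.
#' @return Named list: metabolite -> list of c(lo, hi) ppm intervals.
#' @export
resonance_definitions <- function(library, pad = 0.02,
                                  region = c(0.20, 9.68)) {
  defs <- lapply(library, function(p) {
    lapply(p$positions, function(x) {
      c(max(region[1], x - pad), min(region[2], x + pad))
    })
  })
  names(defs) <- names(library)
  defs
}

#' Per-metabolite resonance integrals
#'
#' Sums the unscaled bucket integrals whose centers fall inside any of a
#' metabolite's defined ppm intervals.
#'
#' @param t An unscaled `bucket_table`.
#' @param defs Named list of interval lists, as from
#'   [resonance_definitions()].
#' @return Samples x metabolites numeric matrix.
#' @export
metabolite_integrals <- function(t, defs) {
  stopifnot(inherits(t, "bucket_table"))
  out <- matrix(0, nrow(t$matrix), length(defs),
                dimnames = list(t$sample_ids, names(defs)))
  for (m in names(defs)) {
    inside <- rep(FALSE, length(t$bucket_centers))
    for (iv in defs[[m]]) {
      inside <- inside |
        (t$bucket_centers >= iv[1] & t$bucket_centers <= iv[2])
    }
    stop_if(!any(inside), "no buckets overlap resonance definition '%s'", m)
    out[, m] <- rowSums(t$matrix[, inside, drop = FALSE])
  }
  out
}

#' Group fold changes relative to a reference class
#'
#' Fold change = mean(group) / mean(reference group), per metabolite.
#'
#' @param integrals Samples x metabolites matrix (unscaled).
#' @param labels Class labels in {-1, +1}.
#' @param reference The reference class label (default -1, the noncancer
#'   group).
#' @return Named numeric vector of fold changes; NA where the reference
#'   mean is zero.
#' @export
fold_changes <- function(integrals, labels, reference = -1) {
  ref <- labels == reference
  stop_if(!any(ref) || all(ref), "both classes must be non-empty")
  ref_mean <- colMeans(integrals[ref, , drop = FALSE])
  grp_mean <- colMeans(integrals[!ref, , drop = FALSE])
  fc <- grp_mean / ref_mean
  fc[ref_mean == 0] <- NA_real_
  fc
}

#' Two-sample Student t test
#'
#' Classical equal-variance t test by default; set `var_equal = FALSE` for
#' Welch.
#'
#' @param a,b Numeric vectors, each with n >= 2.
#' @param var_equal Pool the variance (default TRUE)?
#' @return List with `t`, `p_value`, `df`.
#' @export
student_t <- function(a, b, var_equal = TRUE) {
  stop_if(length(a) < 2L || length(b) < 2L, "each group needs n >= 2")
  stop_if(any(!is.finite(a)) || any(!is.finite(b)), "values must be finite")
  stop_if(stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b),
          "zero pooled variance")
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Pearson correlation with r and r-squared
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List with `r`, `r_squared`, `p_value`.
#' @export
pearson_cor <- function(x, y) {
  stop_if(length(x) != length(y), "x and y lengths differ")
  stop_if(length(x) < 3L, "need n >= 3")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value)
}
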