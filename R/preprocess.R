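#' Reference a spectrum to the lactate doublet
#'
#' Shifts the ppm axis by a constant so that the maximum-intensity point
#' inside the search window sits exactly at the lactate methyl resonance
#' (1.33 ppm). If the window maximum does not rise above the noise floor the
#' spectrum is returned unshifted with a warning flag in its metadata.
#'
#' @param s An [new_spectrum()] object.
#' @param search_window ppm interval searched for the lactate apex.
#' @param target ppm value the apex is moved to.
#' @param min_snr Minimum ratio of window maximum to the spectrum-wide noise
#'   estimate (median absolute deviation) for the shift to be trusted.
#' @return The spectrum with a shifted axis; `meta$reference_shift` records
#'   the applied shift, `meta$reference_failed` flags a skipped shift.
#' @export
reference_to_lactate <- function(s, search_window = c(1.20, 1.45),
                                 target = 1.33, min_snr = 5) {
  stopifnot(inherits(s, "nmr_spectrum"))
  stop_if(search_window[1] < min(s$ppm) || search_window[2] > max(s$ppm),
          "search window [%.2f, %.2f] outside axis extent",
          search_window[1], search_window[2])
  in_win <- s$ppm >= search_window[1] & s$ppm <= search_window[2]
  stop_if(!any(in_win), "no data points inside the search window")
  noise <- stats::mad(s$intensity)
  apex_val <- max(s$intensity[in_win])
  if (apex_val <= 0 || (noise > 0 && apex_val < min_snr * noise)) {
    s$meta$reference_failed <- TRUE
    s$meta$reference_shift <- 0
    return(s)
  }
  apex_ppm <- s$ppm[in_win][which.max(s$intensity[in_win])]
  shift <- target - apex_ppm
  s$ppm <- s$ppm + shift
  s$meta$reference_shift <- shift
  s$meta$reference_failed <- FALSE
  s
}

# Cumulative trapezoid integral evaluated at arbitrary ppm values `at`,
# for an ascending axis x with intensities y. Linear interpolation of y
# inside segments makes the integral exact for piecewise-linear traces.
cumtrap_at <- function(x, y, at) {
  cum <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(x)))
  i <- findInterval(at, x, rightmost.closed = TRUE)
  i <- pmax(pmin(i, length(x) - 1L), 1L)
  frac <- (at - x[i]) / (x[i + 1L] - x[i])
  y_at <- y[i] + frac * (y[i + 1L] - y[i])
  cum[i] + (at - x[i]) * (y[i] + y_at) / 2
}

#' Bucket (bin) a spectrum into fixed-width integrals
#'
#' Divides the region into half-open ascending buckets of the given width
#' and integrates the intensity over each by the trapezoid rule. Buckets
#' that overlap an excluded interval (default: residual water) are dropped.
#'
#' @param s An [new_spectrum()] object.
#' @param region Two ppm values bounding the bucketed region.
#' @param width Bucket width in ppm.
#' @param excluded List of ppm intervals to drop (any overlap drops the
#'   bucket).
#' @return List with `integrals` and bucket `centers` (ascending ppm).
#' @export
bucket_spectrum <- function(s, region = c(0.20, 9.68), width = 0.01,
                            excluded = list(c(4.50, 5.00))) {
  stopifnot(inherits(s, "nmr_spectrum"))
  stop_if(width <= 0, "bucket width must be > 0")
  s <- ascending(s)
  stop_if(region[1] < min(s$ppm) || region[2] > max(s$ppm),
          "bucket region [%.2f, %.2f] outside axis extent [%.2f, %.2f]",
          region[1], region[2], min(s$ppm), max(s$ppm))
  dx <- stats::median(diff(s$ppm))
  stop_if(dx > width / 2 + 1e-12,
          "axis too coarse: fewer than 2 points per %.3g-ppm bucket", width)
  n_buckets <- floor((region[2] - region[1]) / width + 1e-9)
  lefts <- region[1] + (seq_len(n_buckets) - 1L) * width
  rights <- lefts + width
  keep <- rep(TRUE, n_buckets)
  for (ex in excluded) {
    keep <- keep & !(lefts < ex[2] & rights > ex[1])
  }
  ints <- cumtrap_at(s$ppm, s$intensity, rights) -
    cumtrap_at(s$ppm, s$intensity, lefts)
  list(integrals = ints[keep], centers = (lefts + width / 2)[keep])
}

#' Assemble a samples x buckets table from spectra
#'
#' @param spectra List of [new_spectrum()] objects with unique sample ids,
#'   all covering `region`.
#' @param labels Optional class labels (+1/-1), one per spectrum.
#' @param region,width,excluded Passed to [bucket_spectrum()].
#' @return A `bucket_table`: list with `matrix` (samples x buckets),
#'   `bucket_centers`, `bucket_width`, `sample_ids`, `labels`,
#'   `excluded_regions`.
#' @export
assemble_bucket_table <- function(spectra, labels = NULL,
                                  region = c(0.20, 9.68), width = 0.01,
                                  excluded = list(c(4.50, 5.00))) {
  stop_if(length(spectra) == 0L, "no spectra supplied")
  ids <- vapply(spectra, `[[`, "", "sample_id")
  dup <- ids[duplicated(ids)]
  stop_if(length(dup) > 0, "duplicate sample_id: %s", dup[1])
  if (!is.null(labels)) {
    stop_if(length(labels) != length(spectra),
            "one label per spectrum required")
  }
  rows <- vector("list", length(spectra))
  centers <- NULL
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    if (min(s$ppm) > region[1] || max(s$ppm) < region[2]) {
      stop(sprintf("spectrum '%s' does not cover the bucket region", ids[i]),
           call. = FALSE)
    }
    b <- bucket_spectrum(s, region, width, excluded)
    rows[[i]] <- b$integrals
    centers <- b$centers
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  structure(list(matrix = mat, bucket_centers = centers,
                 bucket_width = width, sample_ids = ids, labels = labels,
                 excluded_regions = excluded),
            class = "bucket_table")
}

#' Row-subset a bucket table
#'
#' Keeps the selected samples (rows) and their labels/ids; bucket
#' metadata is carried over unchanged. Useful for modeling/test splits.
#'
#' @param t A `bucket_table` from [assemble_bucket_table()].
#' @param idx Logical or integer row index.
#' @return A `bucket_table` with the selected rows.
#' @export
subset_bucket_table <- function(t, idx) {
  t$matrix <- t$matrix[idx, , drop = FALSE]
  t$sample_ids <- t$sample_ids[idx]
  if (!is.null(t$labels)) t$labels <- t$labels[idx]
  t
}

#' Fit Pareto scaling on a bucket table
#'
#' Pareto scaling centers each bucket and divides by the square root of its
#' sample standard deviation (n-1 denominator), damping but not erasing the
#' intensity differences between large and small peaks. Zero-variance
#' buckets are flagged degenerate and scale to 0 on apply.
#'
#' @param t A `bucket_table` with at least 2 samples.
#' @return A `pareto_scaling` model: `mean`, `scale` (sqrt of sd),
#'   `degenerate` flags, `n_fit`.
#' @export
fit_pareto <- function(t) {
  stopifnot(inherits(t, "bucket_table"))
  stop_if(nrow(t$matrix) < 2L, "Pareto fitting needs >= 2 samples")
  mu <- colMeans(t$matrix)
  sdv <- apply(t$matrix, 2, stats::sd)
  degen <- sdv == 0
  structure(list(mean = mu, scale = sqrt(sdv), degenerate = degen,
                 n_fit = nrow(t$matrix)),
            class = "pareto_scaling")
}

#' Apply a fitted Pareto scaling (never refits)
#'
#' @param t A `bucket_table` with the same bucket count as the model.
#' @param m A `pareto_scaling` from [fit_pareto()].
#' @return The bucket table with `matrix` replaced by its scaled version.
#' @export
apply_pareto <- function(t, m) {
  stopifnot(inherits(t, "bucket_table"), inherits(m, "pareto_scaling"))
  stop_if(ncol(t$matrix) != length(m$mean),
          "bucket count mismatch: table has %d, scaling has %d",
          ncol(t$matrix), length(m$mean))
  sc <- m$scale
  sc[m$degenerate] <- 1  # centered value is 0 for degenerate columns anyway
  x <- sweep(t$matrix, 2, m$mean, "-")
  x <- sweep(x, 2, sc, "/")
  x[, m$degenerate] <- 0
  t$matrix <- x
  t$scaling <- m
  t
}

#' Mean spectrum of a patient group
#'
#' Sums the individual spectra and divides by the number of patients.
#'
#' @param spectra List of spectra on identical axes.
#' @return A spectrum holding the group mean.
#' @export
mean_spectrum <- function(spectra) {
  stop_if(length(spectra) == 0L, "no spectra supplied")
  ax <- spectra[[1]]$ppm
  for (s in spectra[-1]) {
    stop_if(!isTRUE(all.equal(s$ppm, ax)), "spectra have mismatched axes")
  }
  total <- Reduce(`+`, lapply(spectra, `[[`, "intensity"))
  new_spectrum(ax, total / length(spectra), sample_id = "group_mean")
}

#' Difference spectrum (first group mean minus second)
#'
#' @param a,b Mean spectra on identical axes.
#' @return A spectrum holding `a - b` pointwise.
#' @export
difference_spectrum <- function(a, b) {
  stopifnot(inherits(a, "nmr_spectrum"), inherits(b, "nmr_spectrum"))
  stop_if(!isTRUE(all.equal(a$ppm, b$ppm)), "spectra have mismatched axes")
  new_spectrum(a$ppm, a$intensity - b$intensity, sample_id = "difference")
}
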