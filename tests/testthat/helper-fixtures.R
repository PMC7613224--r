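# Shared fixtures, built in code at test time.

# Small synthetic cohort at reduced axis resolution (tests only need the
# bucket grid to be well resolved, ~4 points per 0.01-ppm bucket).
small_cohort <- function(n = 60, prevalence = 0.5, log2fc = 0.7, seed = 1,
                         points = 4096, ...) {
  eff <- if (log2fc == 0) {
    setNames(numeric(1), "glucose")  # named zero effect = null cohort
  } else {
    default_effects(log2fc)
  }
  simulate_cohort(cohort_config(
    n_samples = n, prevalence = prevalence, effects = eff,
    points_per_spectrum = points, seed = seed, ...))
}

# Bucket table with a perfectly separable single informative bucket plus
# pure-noise buckets: two clusters far apart along bucket 1.
separable_table <- function(n_per_class = 20, n_buckets = 30, gap = 10,
                            seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  m <- matrix(rnorm(n * n_buckets), n, n_buckets)
  y <- rep(c(-1L, 1L), each = n_per_class)
  m[, 1] <- m[, 1] * 0.2 + gap * (y == 1L)
  structure(list(matrix = m,
                 bucket_centers = seq(0.205, by = 0.01,
                                      length.out = n_buckets),
                 bucket_width = 0.01,
                 sample_ids = sprintf("S%02d", seq_len(n)),
                 labels = y, excluded_regions = list()),
            class = "bucket_table")
}

# A bucket_table wrapper around an arbitrary matrix.
as_bucket_table <- function(m, labels = NULL) {
  structure(list(matrix = m,
                 bucket_centers = seq(0.205, by = 0.01,
                                      length.out = ncol(m)),
                 bucket_width = 0.01,
                 sample_ids = sprintf("S%03d", seq_len(nrow(m))),
                 labels = labels, excluded_regions = list()),
            class = "bucket_table")
}

# Brute-force one-sided Fisher p by enumerating all 2x2 tables with the
# observed margins (hypergeometric tail), independent of fisher_exact().
fisher_greater_bruteforce <- function(tp, fp, fn, tn) {
  # margins: row1 = tp + fn (true positives), col1 = tp + fp (predicted pos)
  r1 <- tp + fn
  c1 <- tp + fp
  N <- tp + fp + fn + tn
  ks <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, N - r1, c1)
  sum(probs[ks >= tp])
}

# Pair-counting AUC oracle: concordant pairs + half ties.
auc_paircount <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels <= 0]
  total <- 0
  for (x in pos) total <- total + sum(x > neg) + 0.5 * sum(x == neg)
  total / (length(pos) * length(neg))
}
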