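#' Repeated stratified external cross-validation
#'
#' The external validation loop: per repeat, a stratified k-fold partition;
#' per fold, the full training procedure — Pareto scaling fit and internal
#' selection of orthogonal components — runs on the training portion only,
#' so the classifier is blinded to the held-out fold. Held-out samples are
#' classified at score threshold 0 and per-model sensitivity, specificity
#' and accuracy recorded.
#'
#' @param t An unscaled `bucket_table` with labels in {-1, +1}.
#' @param k Folds per repeat (default 10).
#' @param repeats Number of repeats; `k * repeats` models are trained
#'   (the study-scale configuration is 100 repeats = 1,000 models).
#' @param seed Integer seed; repeat r is reproducible in isolation from
#'   (seed, r).
#' @param max_ortho Maximum orthogonal components for internal selection;
#'   `select = FALSE` skips selection and uses `n_ortho` directly.
#' @param internal_k Internal CV folds for component selection (default 7).
#' @param select Run internal component selection per fold?
#' @param n_ortho Fixed orthogonal component count when `select = FALSE`.
#' @return A `cv_distribution`: metric vectors of length k*repeats
#'   (`sensitivity`, `specificity`, `accuracy`, `balanced_accuracy`),
#'   `scores` (per repeat, pooled out-of-fold score per sample), and the
#'   `scheme` descriptor.
#' @export
external_cv <- function(t, k = 10L, repeats = 10L, seed = 1L,
                        max_ortho = 9L, internal_k = 7L,
                        select = TRUE, n_ortho = 0L) {
  stopifnot(inherits(t, "bucket_table"))
  y <- t$labels
  stop_if(is.null(y), "bucket table has no labels")
  stop_if(length(unique(y)) != 2L, "labels must contain both classes")
  n <- length(y)

  n_models <- k * repeats
  sens <- spec <- acc <- numeric(n_models)
  scores <- matrix(NA_real_, nrow = repeats, ncol = n,
                   dimnames = list(NULL, t$sample_ids))
  m <- 0L
  for (r in seq_len(repeats)) {
    rseed <- child_seed(seed, r)
    folds <- valid_folds(y, k, rseed)
    for (f in seq_len(k)) {
      hold <- folds == f
      train <- subset_bucket_table(t, !hold)
      test <- subset_bucket_table(t, hold)
      scaling <- fit_pareto(train)
      Xtr <- apply_pareto(train, scaling)$matrix
      Xte <- apply_pareto(test, scaling)$matrix
      a <- if (select) {
        select_n_orthogonal(Xtr, y[!hold], max_ortho, internal_k,
                            seed = child_seed(rseed, f))$n_ortho
      } else n_ortho
      fit <- fit_opls(Xtr, y[!hold], a)
      sc <- predict_scores(fit, Xte)
      scores[r, hold] <- sc
      pred <- ifelse(sc >= 0, 1L, -1L)
      cc <- confusion_counts_from(pred, y[hold])
      m <- m + 1L
      sens[m] <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
      spec[m] <- if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else NA_real_
      acc[m] <- (cc$tp + cc$tn) / sum(hold)
    }
  }
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 balanced_accuracy = (sens + spec) / 2,
                 scores = scores,
                 scheme = list(k = k, repeats = repeats, seed = seed,
                               max_ortho = max_ortho, select = select)),
            class = "cv_distribution")
}

#' Permutation null distribution for the external CV metrics
#'
#' Each permutation shuffles the class labels once and reruns the full
#' external cross-validation, contributing its per-model metrics to the
#' null pool.
#'
#' @param t An unscaled `bucket_table` with labels.
#' @param n_perm Number of label permutations.
#' @param k,repeats_per_perm,seed,... Passed through to [external_cv()].
#' @return A `cv_distribution` pooling all permutations
#'   (`n_perm * k * repeats_per_perm` models).
#' @export
permutation_null <- function(t, n_perm = 100L, k = 10L,
                             repeats_per_perm = 1L, seed = 1L, ...) {
  stopifnot(inherits(t, "bucket_table"))
  out <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    pseed <- child_seed(seed, 1000L + p)
    tp <- t
    tp$labels <- with_seed(pseed, sample(t$labels))
    out[[p]] <- external_cv(tp, k = k, repeats = repeats_per_perm,
                            seed = child_seed(pseed, 1L), ...)
  }
  structure(list(
    sensitivity = unlist(lapply(out, `[[`, "sensitivity")),
    specificity = unlist(lapply(out, `[[`, "specificity")),
    accuracy = unlist(lapply(out, `[[`, "accuracy")),
    balanced_accuracy = unlist(lapply(out, `[[`, "balanced_accuracy")),
    scores = NULL,
    scheme = list(k = k, repeats = repeats_per_perm, n_perm = n_perm,
                  seed = seed)),
    class = "cv_distribution")
}

#' Two-sample Kolmogorov-Smirnov comparison of metric distributions
#'
#' Compares the real cross-validation metric distribution against its
#' permutation null via the maximum empirical-CDF gap, two-sided. The
#' exact p-value is enumerated when both samples have at most 10 values;
#' otherwise the asymptotic Kolmogorov distribution is used.
#'
#' @param real,null Numeric metric vectors (length >= 2 each).
#' @return List with `D`, `p_value`, `sidedness`.
#' @export
ks_compare <- function(real, null) {
  real <- real[is.finite(real)]
  null <- null[is.finite(null)]
  stop_if(length(real) < 2L || length(null) < 2L,
          "both inputs need >= 2 finite values")
  exact <- length(real) <= 10L && length(null) <= 10L
  kt <- suppressWarnings(
    stats::ks.test(real, null, alternative = "two.sided", exact = exact))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value),
       sidedness = "two-sided")
}
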