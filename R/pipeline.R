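#' Split a cohort into modeling and independent test sets by referral order
#'
#' Deterministic: samples are sorted by referral order and the first
#' ceiling(fraction * n) (or an explicit count) form the modeling set; the
#' rest are reserved as the independent test set.
#'
#' @param metadata Data frame with columns `sample_id` and `referral_order`
#'   (unique).
#' @param modeling_fraction Fraction assigned to the modeling set (default
#'   two thirds).
#' @param counts Optional explicit c(modeling, test) counts; overrides the
#'   fraction (e.g. c(192, 92) at the study's n = 284).
#' @return List with `modeling` and `test` sample-id vectors.
#' @export
split_by_order <- function(metadata, modeling_fraction = 2 / 3,
                           counts = NULL) {
  stop_if(anyDuplicated(metadata$referral_order) > 0,
          "referral_order values must be unique")
  ord <- order(metadata$referral_order)
  ids <- metadata$sample_id[ord]
  n <- length(ids)
  n_model <- if (!is.null(counts)) {
    stop_if(sum(counts) != n, "explicit counts must sum to n")
    counts[1]
  } else {
    ceiling(modeling_fraction * n)
  }
  list(modeling = ids[seq_len(n_model)],
       test = ids[setdiff(seq_len(n), seq_len(n_model))])
}

#' Run the full classification study on a cohort
#'
#' Composes every stage in order: bucketing and assembly, referral-order
#' split, repeated external cross-validation with a permutation null and
#' Kolmogorov-Smirnov comparison on the modeling set, final OPLS-DA fit
#' with internal component selection and VIP scoring, ROC threshold
#' selection (closest-to-top-left) on the modeling set, one-shot evaluation
#' of the independent test set with Fisher exact test and Wilson intervals,
#' and a univariate panel over the VIP-significant metabolites.
#'
#' @param cohort A cohort from [simulate_cohort()], or a list with
#'   `spectra`, `labels`, `referral_order`.
#' @param library Peak library (for mapping VIP buckets to metabolites).
#' @param modeling_counts Optional explicit c(modeling, test) sizes.
#' @param k,repeats,n_perm,max_ortho Cross-validation scheme knobs.
#' @param threshold_source "cv" (pooled cross-validated out-of-fold
#'   modeling-set scores; default, avoids optimism) or "fit" (refit
#'   modeling-set scores).
#' @param region,width,excluded Bucketing parameters.
#' @param seed Integer seed for all resampling.
#' @return A report bundle (list) with elements `split`, `cv`, `null`,
#'   `ks`, `model`, `vip`, `threshold`, `modeling_eval`, `test_eval`,
#'   `auc_comparison`, `univariate`, `config`.
#' @export
run_study <- function(cohort, library = build_peak_library(),
                      modeling_counts = NULL,
                      k = 10L, repeats = 10L, n_perm = 20L, max_ortho = 9L,
                      threshold_source = c("cv", "fit"),
                      region = c(0.20, 9.68), width = 0.01,
                      excluded = list(c(4.50, 5.00)), seed = 1L) {
  threshold_source <- match.arg(threshold_source)

  tab <- assemble_bucket_table(cohort$spectra, cohort$labels,
                               region = region, width = width,
                               excluded = excluded)
  meta <- data.frame(sample_id = tab$sample_ids,
                     referral_order = cohort$referral_order)
  split <- split_by_order(meta, counts = modeling_counts)
  mod_idx <- tab$sample_ids %in% split$modeling
  tab_mod <- subset_bucket_table(tab, mod_idx)
  tab_test <- subset_bucket_table(tab, !mod_idx)
  stop_if(length(unique(tab_mod$labels)) != 2L,
          "modeling set must contain both classes")

  # External validation on the modeling set only
  cvd <- external_cv(tab_mod, k = k, repeats = repeats, seed = seed,
                     max_ortho = max_ortho)
  nulld <- permutation_null(tab_mod, n_perm = n_perm, k = k,
                            repeats_per_perm = 1L,
                            seed = child_seed(seed, 2L),
                            max_ortho = max_ortho)
  ks <- list(
    accuracy = ks_compare(cvd$accuracy, nulld$accuracy),
    sensitivity = ks_compare(cvd$sensitivity, nulld$sensitivity),
    specificity = ks_compare(cvd$specificity, nulld$specificity))

  # Final model on the full modeling set
  scaling <- fit_pareto(tab_mod)
  Xmod <- apply_pareto(tab_mod, scaling)$matrix
  sel <- select_n_orthogonal(Xmod, tab_mod$labels, max_ortho, 7L,
                             seed = child_seed(seed, 3L))
  model <- fit_opls(Xmod, tab_mod$labels, sel$n_ortho)
  vip_scores <- vip(model)

  # Threshold from the modeling set
  mod_scores <- if (threshold_source == "cv") {
    colMeans(cvd$scores)  # mean out-of-fold score per sample over repeats
  } else {
    model$fitted
  }
  roc_mod <- roc_curve(mod_scores, tab_mod$labels)
  thr <- optimal_threshold_topleft(roc_mod)
  cc_mod <- confusion_counts_from(mod_scores >= thr, tab_mod$labels)
  modeling_eval <- evaluate_counts(cc_mod)
  modeling_eval$roc <- roc_mod

  # Independent test set, read exactly once, after threshold selection
  Xtest <- apply_pareto(tab_test, scaling)$matrix
  test_scores <- predict_scores(model, Xtest)
  cc_test <- confusion_counts_from(test_scores >= thr, tab_test$labels)
  test_eval <- evaluate_counts(cc_test)
  test_eval$fisher <- fisher_exact(cc_test)
  test_eval$roc <- roc_curve(test_scores, tab_test$labels)

  auc_comparison <- z_compare_auc(mod_scores, tab_mod$labels,
                                  test_scores, tab_test$labels)

  # Univariate panel over VIP-significant metabolites
  defs <- resonance_definitions(library, region = region)
  sig_centers <- tab$bucket_centers[vip_scores$significant]
  sig_mets <- names(defs)[vapply(defs, function(iv_list) {
    any(vapply(iv_list, function(iv) {
      any(sig_centers >= iv[1] & sig_centers <= iv[2])
    }, logical(1)))
  }, logical(1))]
  univariate <- NULL
  if (length(sig_mets) > 0) {
    ints <- metabolite_integrals(tab, defs[sig_mets])
    fc <- fold_changes(ints, tab$labels, reference = -1)
    tests <- lapply(sig_mets, function(m) {
      student_t(ints[tab$labels == 1, m], ints[tab$labels == -1, m])
    })
    univariate <- data.frame(
      metabolite = sig_mets,
      fold_change = unname(fc[sig_mets]),
      t = vapply(tests, `[[`, 0, "t"),
      p_value = vapply(tests, `[[`, 0, "p_value"))
  }

  list(split = split, cv = cvd, null = nulld, ks = ks,
       model = model, component_selection = sel, vip = vip_scores,
       bucket_centers = tab$bucket_centers,
       threshold = thr, modeling_eval = modeling_eval,
       test_eval = test_eval, auc_comparison = auc_comparison,
       univariate = univariate,
       config = list(k = k, repeats = repeats, n_perm = n_perm,
                     max_ortho = max_ortho, seed = seed,
                     threshold_source = threshold_source,
                     region = region, width = width, excluded = excluded))
}

# Metric panel + Wilson intervals for a confusion table.
evaluate_counts <- function(cc) {
  panel <- confusion_panel(cc)
  list(counts = cc, metrics = panel,
       wilson = list(
         sensitivity = wilson_interval(cc$tp, cc$tp + cc$fn),
         specificity = wilson_interval(cc$tn, cc$tn + cc$fp),
         npv = wilson_interval(cc$tn, cc$tn + cc$fn),
         ppv = wilson_interval(cc$tp, cc$tp + cc$fp)))
}
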