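#' ROC curve from scores and labels
#'
#' Classification rule: positive if score >= threshold. Thresholds are the
#' distinct observed scores (descending) plus +Inf, so the curve runs from
#' (0, 0) to (1, 1). AUC is the trapezoid area, identical to the
#' Mann-Whitney U statistic divided by n_pos * n_neg (ties credited 0.5).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Class labels in {-1, +1} (or logical, TRUE = positive).
#' @return A `roc_curve`: `thresholds`, `sensitivity`,
#'   `one_minus_specificity`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_positive(labels)
  stop_if(!any(pos) || all(pos), "both classes must be present")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(th) sum(scores[pos] >= th) / n_pos, 0)
  fpr <- vapply(thr, function(th) sum(scores[!pos] >= th) / n_neg, 0)
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens,
                 one_minus_specificity = fpr, auc = auc),
            class = "roc_curve")
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels > 0
}

#' Optimal threshold: point closest to the top-left ROC corner
#'
#' Minimizes the Euclidean distance sqrt((1 - sens)^2 + (1 - spec)^2);
#' ties go to the higher-specificity point, then the higher threshold.
#'
#' @param roc A `roc_curve`.
#' @return The selected score threshold.
#' @export
optimal_threshold_topleft <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  d2 <- (1 - roc$sensitivity)^2 + roc$one_minus_specificity^2
  cand <- which(d2 <= min(d2) + 1e-12)
  cand <- cand[roc$one_minus_specificity[cand] ==
                 min(roc$one_minus_specificity[cand])]
  max(roc$thresholds[cand])
}

#' Confusion counts
#'
#' @param tp,fp,fn,tn Nonnegative integer cell counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stop_if(any(v < 0), "confusion counts must be nonnegative")
  structure(as.list(v), class = "confusion_counts")
}

#' Confusion counts from predicted and true classes
#'
#' @param pred,truth Vectors in {-1, +1} (or logical).
#' @return A `confusion_counts` list.
#' @export
confusion_counts_from <- function(pred, truth) {
  p <- as_positive(pred)
  t <- as_positive(truth)
  confusion_counts(tp = sum(p & t), fp = sum(p & !t),
                   fn = sum(!p & t), tn = sum(!p & !t))
}

#' Diagnostic metric panel from a confusion table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp),
#' NPV tn/(tn+fn), accuracy, balanced accuracy (sensitivity +
#' specificity)/2, and F1 = 2TP/(2TP + FP + FN). A metric whose
#' denominator is zero is returned as NA (undefined).
#'
#' @param c A `confusion_counts`.
#' @return Named numeric vector of the seven metrics.
#' @export
confusion_panel <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rat(c$tp, c$tp + c$fn)
  spec <- rat(c$tn, c$tn + c$fp)
  n <- c$tp + c$fp + c$fn + c$tn
  c(sensitivity = sens,
    specificity = spec,
    ppv = rat(c$tp, c$tp + c$fp),
    npv = rat(c$tn, c$tn + c$fn),
    accuracy = rat(c$tp + c$tn, n),
    balanced_accuracy = (sens + spec) / 2,
    f1 = rat(2 * c$tp, 2 * c$tp + c$fp + c$fn))
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,n Integer counts, 0 <= successes <= n, n >= 1.
#' @param level Confidence level (default 0.95).
#' @return List with `point`, `lower`, `upper`, `level`.
#' @export
wilson_interval <- function(successes, n, level = 0.95) {
  stop_if(n < 1, "n must be >= 1")
  stop_if(successes < 0 || successes > n, "successes must be in [0, n]")
  z <- stats::qnorm((1 + level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  list(point = p, lower = max(0, center - half),
       upper = min(1, center + half), level = level)
}

#' Fisher exact test on a confusion table
#'
#' Tests association between predicted and true class in the 2x2 table
#' (tp, fn; fp, tn) by hypergeometric enumeration. Reports the one-sided
#' (classification better than chance) and two-sided (point-probability
#' rule) p-values.
#'
#' @param c A `confusion_counts`.
#' @return List with `p_greater` and `p_two_sided`.
#' @export
fisher_exact <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  m <- matrix(c(c$tp, c$fp, c$fn, c$tn), nrow = 2)
  list(p_greater = stats::fisher.test(m, alternative = "greater")$p.value,
       p_two_sided = stats::fisher.test(m, alternative = "two.sided")$p.value)
}

#' Z comparison of two proportions (or one proportion against a constant)
#'
#' Pooled-variance two-proportion Z test; with a single (successes, n)
#' pair, a one-sample Z against `p0` (default 0.5, e.g. a sex ratio
#' against 1:1).
#'
#' @param x1,n1 First successes / trials.
#' @param x2,n2 Optional second pair.
#' @param p0 Null proportion for the one-sample variant.
#' @return List with `z` and two-sided `p_value`.
#' @export
z_compare_proportions <- function(x1, n1, x2 = NULL, n2 = NULL, p0 = 0.5) {
  p1 <- x1 / n1
  if (is.null(x2)) {
    se <- sqrt(p0 * (1 - p0) / n1)
    stop_if(se == 0, "degenerate variance")
    z <- (p1 - p0) / se
  } else {
    p2 <- x2 / n2
    pool <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
    stop_if(se == 0, "degenerate variance")
    z <- (p1 - p2) / se
  }
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

# DeLong structural components: per-positive and per-negative placement
# values whose means equal the AUC.
delong_components <- function(scores, labels) {
  pos <- scores[as_positive(labels)]
  neg <- scores[!as_positive(labels)]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' Z comparison of two unpaired ROC AUCs (DeLong variance)
#'
#' @param scores1,labels1 First score/label set.
#' @param scores2,labels2 Second score/label set (independent samples).
#' @return List with `auc1`, `auc2`, `z`, two-sided `p_value`.
#' @export
z_compare_auc <- function(scores1, labels1, scores2, labels2) {
  a <- delong_components(scores1, labels1)
  b <- delong_components(scores2, labels2)
  var_a <- stats::var(a$v10) / length(a$v10) + stats::var(a$v01) / length(a$v01)
  var_b <- stats::var(b$v10) / length(b$v10) + stats::var(b$v01) / length(b$v01)
  se <- sqrt(var_a + var_b)
  z <- if (a$auc == b$auc) 0 else {
    stop_if(se == 0, "degenerate AUC variance")
    (a$auc - b$auc) / se
  }
  list(auc1 = a$auc, auc2 = b$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}
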