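test_that("ROC curve endpoints, AUC and symmetry behave", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity[1], 0)
  expect_equal(r$one_minus_specificity[1], 0)
  expect_equal(r$sensitivity[length(r$sensitivity)], 1)
  expect_equal(r$one_minus_specificity[length(r$sensitivity)], 1)

  # 3 of 4 pairs concordant
  r2 <- roc_curve(c(0.9, 0.4, 0.8, 0.3), c(1, 1, -1, -1))
  expect_equal(r2$auc, 0.75)

  # inverting labels mirrors the AUC
  r3 <- roc_curve(c(0.9, 0.4, 0.8, 0.3), c(-1, -1, 1, 1))
  expect_equal(r3$auc, 1 - r2$auc)

  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals the Mann-Whitney pair-counting oracle", {
  for (i in 1:100) {
    set.seed(i)
    n <- sample(6:25, 1)
    labels <- c(rep(1, 3), rep(-1, 3),
                sample(c(-1, 1), n - 6, replace = TRUE))
    scores <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(roc_curve(scores, labels)$auc, auc_paircount(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC and curve agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- rnorm(40)
  labels <- rep(c(-1, 1), 20)
  ours <- roc_curve(scores, labels)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("the stored AUC equals the trapezoid area of the stored points", {
  set.seed(4)
  r <- roc_curve(round(rnorm(30), 1), rep(c(-1, 1), 15))
  x <- r$one_minus_specificity
  y <- r$sensitivity
  expect_equal(r$auc, sum(diff(x) * (y[-1] + y[-length(y)]) / 2))
})

test_that("top-left threshold selection matches brute-force enumeration", {
  # perfect separation: distance 0 at the separating cut
  r <- roc_curve(c(3, 2, 1, 0), c(1, 1, -1, -1))
  thr <- optimal_threshold_topleft(r)
  expect_equal(min((1 - r$sensitivity)^2 + r$one_minus_specificity^2), 0)
  expect_equal(thr, 2)

  # one mislabel: verify against exhaustive distance search
  scores <- c(3, 2, 1, 0)
  labels <- c(1, -1, 1, -1)
  r2 <- roc_curve(scores, labels)
  d <- sqrt((1 - r2$sensitivity)^2 + r2$one_minus_specificity^2)
  brute <- r2$thresholds[which(d == min(d))]
  expect_true(optimal_threshold_topleft(r2) %in% brute)

  # symmetric tie resolves toward higher specificity, then higher threshold
  r3 <- roc_curve(c(2, 1), c(1, -1) * -1)  # AUC 0: ties abound
  expect_equal(optimal_threshold_topleft(r3),
               max(r3$thresholds[
                 (1 - r3$sensitivity)^2 + r3$one_minus_specificity^2 <=
                   min((1 - r3$sensitivity)^2 +
                         r3$one_minus_specificity^2) + 1e-12]))
})

test_that("confusion panel reproduces the closed-form diagnostics", {
  cc <- confusion_counts(tp = 5, fp = 25, fn = 2, tn = 60)
  p <- confusion_panel(cc)
  expect_equal(round(100 * p[["sensitivity"]]), 71)  # 5/7
  expect_equal(round(100 * p[["npv"]]), 97)          # 60/62
  expect_equal(p[["f1"]], 10 / 37, tolerance = 1e-12)
  expect_equal(p[["specificity"]], 60 / 85, tolerance = 1e-12)

  # balanced accuracy is the arithmetic mean of sensitivity and specificity
  expect_equal((0.94 + 0.82) / 2, 0.88)
  expect_equal(p[["balanced_accuracy"]],
               (p[["sensitivity"]] + p[["specificity"]]) / 2)

  # degenerate table: undefined metrics are NA-flagged
  p0 <- confusion_panel(confusion_counts(0, 0, 0, 0))
  expect_true(all(is.na(p0)))
})

test_that("swapping class labels swaps sensitivity/specificity and ppv/npv", {
  cc <- confusion_counts(tp = 7, fp = 3, fn = 2, tn = 11)
  sw <- confusion_counts(tp = 11, fp = 2, fn = 3, tn = 7)
  a <- confusion_panel(cc)
  b <- confusion_panel(sw)
  expect_equal(a[["sensitivity"]], b[["specificity"]])
  expect_equal(a[["ppv"]], b[["npv"]])
  expect_equal(a[["accuracy"]], b[["accuracy"]])
})

test_that("Wilson intervals reproduce printed confidence limits", {
  w1 <- wilson_interval(16, 17)
  expect_equal(round(100 * w1$lower), 73)
  expect_equal(round(100 * w1$upper), 99)

  w2 <- wilson_interval(7, 8)
  expect_equal(round(100 * w2$lower), 53)
  expect_equal(round(100 * w2$upper), 98)

  w3 <- wilson_interval(0, 10)
  expect_equal(w3$lower, 0)

  # bounds always bracket the point estimate inside [0, 1]
  for (i in 1:50) {
    set.seed(i)
    n <- sample(1:40, 1)
    x <- sample(0:n, 1)
    w <- wilson_interval(x, n)
    expect_true(w$lower <= w$point && w$point <= w$upper)
    expect_true(w$lower >= 0 && w$upper <= 1)
  }
  expect_error(wilson_interval(3, 0), "n must be")
})

test_that("Fisher exact p-values match hypergeometric enumeration", {
  f <- fisher_exact(confusion_counts(tp = 2, fp = 0, fn = 0, tn = 2))
  expect_equal(f$p_two_sided, 1 / 3, tolerance = 1e-12)

  f2 <- fisher_exact(confusion_counts(tp = 5, fp = 5, fn = 5, tn = 5))
  expect_equal(f2$p_two_sided, 1, tolerance = 1e-12)

  f3 <- fisher_exact(confusion_counts(tp = 5, fp = 25, fn = 2, tn = 60))
  expect_equal(f3$p_greater, fisher_greater_bruteforce(5, 25, 2, 60),
               tolerance = 1e-12)
  expect_lt(f3$p_greater, 0.05)
  expect_equal(f3$p_greater, 0.035, tolerance = 1e-2)

  # brute-force margin enumeration for all tables with N <= 30
  set.seed(9)
  for (i in 1:60) {
    cells <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    f <- fisher_exact(confusion_counts(cells[1], cells[2], cells[3],
                                       cells[4]))
    expect_equal(f$p_greater,
                 fisher_greater_bruteforce(cells[1], cells[2], cells[3],
                                           cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("proportion Z tests flag the skewed sex ratio and nothing else", {
  # 161 of 284 female vs a 1:1 ratio: Z = (161/284 - 0.5)/sqrt(0.25/284)
  sex <- z_compare_proportions(161, 284)
  expect_equal(sex$z, (161 / 284 - 0.5) / sqrt(0.25 / 284), tolerance = 1e-12)
  expect_equal(sex$z, 2.2548, tolerance = 1e-4)
  expect_lt(sex$p_value, 0.05)

  eq <- z_compare_proportions(50, 100, 50, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
})

test_that("DeLong AUC comparison is null for identical curves and matches pROC", {
  set.seed(5)
  scores <- rnorm(30)
  labels <- rep(c(-1, 1), 15)
  same <- z_compare_auc(scores, labels, scores, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  skip_if_not_installed("pROC")
  scores2 <- rnorm(40) + 0.8 * rep(c(0, 1), 20)
  labels2 <- rep(c(-1, 1), 20)
  ours <- z_compare_auc(scores, labels, scores2, labels2)
  ref <- suppressMessages(pROC::roc.test(
    pROC::roc(labels, scores, quiet = TRUE),
    pROC::roc(labels2, scores2, quiet = TRUE),
    method = "delong", paired = FALSE))
  # same statistic as pROC's DeLong; our p uses the normal reference
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)), tolerance = 1e-8)
  expect_equal(ours$p_value, 2 * pnorm(-abs(ours$z)), tolerance = 1e-12)
})
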