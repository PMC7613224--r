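random_xy <- function(n, j, seed) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * j), n, j), scale = FALSE)
  y <- rep(c(-1, 1), length.out = n)
  X[, 1] <- X[, 1] + y  # some signal
  list(X = scale(X, scale = FALSE), y = y)
}

test_that("with no orthogonal components the weight is proportional to X'y", {
  d <- random_xy(24, 15, 1)
  m <- fit_opls(d$X, d$y, 0)
  w_ref <- crossprod(d$X, d$y)[, 1]
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(m$w, w_ref, tolerance = 1e-12)
  expect_equal(sqrt(sum(m$w^2)), 1, tolerance = 1e-12)
})

test_that("an orthogonal component absorbs structured y-unrelated variation", {
  set.seed(2)
  n <- 40
  y <- rep(c(-1, 1), each = n / 2)
  signal <- matrix(rnorm(n * 10, sd = 0.1), n, 10) + outer(y, rep(1, 10))
  # confound: strong variation along a direction orthogonal to y
  conf <- rnorm(n)
  conf <- conf - mean(conf)
  conf <- conf - y * sum(conf * y) / sum(y * y)
  X <- scale(cbind(signal, conf * 5), scale = FALSE)

  clean <- scale(cbind(signal, 0 * conf), scale = FALSE)
  m0 <- fit_opls(clean, y, 0)
  m1 <- fit_opls(X, y, 1)
  # after removing the orthogonal component, scores rank samples the same
  expect_gt(cor(m1$t, m0$t), 0.99)
  # orthogonality of stored components
  expect_lt(abs(sum(m1$w * m1$W_o[, 1])), 1e-8)
  expect_lt(abs(cor(m1$t, m1$T_o[, 1])), 1e-6)
})

test_that("linearly separable clusters classify perfectly at threshold 0", {
  t <- separable_table(n_per_class = 15, seed = 3)
  X <- apply_pareto(t, fit_pareto(t))$matrix
  m <- fit_opls(X, t$labels, 0)
  pred <- ifelse(m$fitted >= 0, 1L, -1L)
  expect_identical(pred, t$labels)
})

test_that("prediction is self-consistent, linear and shape-checked", {
  d <- random_xy(30, 12, 4)
  m <- fit_opls(d$X, d$y, 2)
  # training matrix reproduces training fitted values
  expect_equal(predict_scores(m, d$X), m$fitted, tolerance = 1e-10)
  # duplicated row -> duplicated score; zero row -> zero score
  X2 <- rbind(d$X[1, ], d$X[1, ], 0)
  sc <- predict_scores(m, X2)
  expect_equal(sc[1], sc[2])
  expect_equal(sc[3], 0)
  expect_error(predict_scores(m, d$X[, 1:5]), "mismatch")
})

test_that("degenerate responses are rejected", {
  d <- random_xy(20, 8, 5)
  expect_error(fit_opls(d$X, rep(1, 20), 0), "variance")
  expect_error(fit_opls(matrix(0, 20, 8), d$y, 0), "signal")
})

test_that("NIPALS with 0 orthogonal components matches a reference PLS1", {
  skip_if_not_installed("mixOmics")
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30; j <- 50
    X <- matrix(rnorm(n * j), n, j)
    y <- rep(c(-1, 1), length.out = n)
    X[, 1:5] <- X[, 1:5] + y
    Xc <- scale(X, scale = FALSE)
    m <- fit_opls(Xc, y, 0)
    ref <- mixOmics::pls(Xc, y, ncomp = 1, scale = FALSE, mode = "regression")
    expect_gt(abs(cor(m$t, ref$variates$X[, 1])), 1 - 1e-8)
  }
})

test_that("permuting bucket order permutes w and leaves scores unchanged", {
  d <- random_xy(26, 18, 6)
  m <- fit_opls(d$X, d$y, 1)
  perm <- sample(18)
  mp <- fit_opls(d$X[, perm], d$y, 1)
  expect_equal(mp$w, m$w[perm], tolerance = 1e-10)
  expect_equal(mp$fitted, m$fitted, tolerance = 1e-10)
  expect_equal(predict_scores(mp, d$X[, perm]),
               predict_scores(m, d$X), tolerance = 1e-10)
})

test_that("Q2 is 1 for perfect prediction and 0 for the mean predictor", {
  # perfectly separable, huge gap: held-out predictions hit y almost exactly
  t <- separable_table(n_per_class = 14, n_buckets = 5, gap = 50, seed = 7)
  X <- scale(t$matrix, scale = FALSE)
  q2 <- q2_internal_cv(X, t$labels, 0, k = 7, seed = 1)
  expect_gt(q2, 0.95)

  # permuted labels: Q2 at or below 0 on average
  set.seed(8)
  q2_null <- vapply(1:20, function(s) {
    set.seed(s)
    yp <- sample(t$labels)
    q2_internal_cv(X, yp, 0, k = 7, seed = s)
  }, 0)
  expect_lte(mean(q2_null), 0)
})

test_that("component selection scans 0..9 and favors parsimony on clean data", {
  d <- random_xy(40, 10, 9)
  sel <- select_n_orthogonal(d$X, d$y, max_ortho = 9, seed = 1)
  expect_length(sel$q2, 10)
  expect_equal(names(sel$q2), as.character(0:9))
  # ties broken toward fewer components
  expect_equal(sel$n_ortho, unname(which.max(sel$q2) - 1L))

  # pure predictive structure: majority of seeds select few components
  picks <- vapply(1:20, function(s) {
    dd <- random_xy(40, 10, 100 + s)
    select_n_orthogonal(dd$X, dd$y, max_ortho = 9, seed = s)$n_ortho
  }, integer(1))
  expect_gte(mean(picks <= 1), 0.5)
})

test_that("a strong orthogonal confound drives component selection above 0", {
  picks <- vapply(1:20, function(s) {
    set.seed(200 + s)
    n <- 40
    y <- rep(c(-1, 1), each = n / 2)
    X <- matrix(rnorm(n * 10, sd = 0.5), n, 10) + outer(y, rep(1, 10))
    conf <- rnorm(n)
    conf <- conf - mean(conf)
    conf <- conf - y * sum(conf * y) / sum(y * y)
    # confound loads across every variable, swamping the class signal
    X <- X + outer(conf, rnorm(10, sd = 3))
    select_n_orthogonal(scale(X, scale = FALSE), y, max_ortho = 9,
                        seed = s)$n_ortho
  }, integer(1))
  expect_gte(mean(picks >= 1), 0.5)
})

test_that("VIP follows sqrt(J)|w| with unit mean square and a VIP>2 flag", {
  # one informative bucket out of four: w = (1,0,0,0) -> VIP = (2,0,0,0)
  y <- rep(c(-1, 1), each = 10)
  X <- cbind(y, 0, 0, 0) + 0
  m <- fit_opls(scale(X, scale = FALSE), y, 0)
  v <- vip(m)
  expect_equal(v$vip, c(2, 0, 0, 0), tolerance = 1e-10)
  expect_identical(v$significant, 1L)

  # uniform weights: all VIP exactly 1, none significant
  Xu <- matrix(rep(y, 4), ncol = 4) + matrix(rnorm(80, sd = 1e-6), ncol = 4)
  vu <- vip(fit_opls(scale(Xu, scale = FALSE), y, 0))
  expect_equal(vu$vip, rep(1, 4), tolerance = 1e-3)
  expect_length(vu$significant, 0)

  # normalization identity on arbitrary models
  d <- random_xy(30, 23, 10)
  expect_equal(mean(vip(fit_opls(d$X, d$y, 2))$vip^2), 1, tolerance = 1e-8)
})
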