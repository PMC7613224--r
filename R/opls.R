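#' Fit a single-response OPLS-DA model by NIPALS
#'
#' Orthogonal partial least squares discriminant analysis for a binary
#' response coded y in {-1, +1}. The predictive weight is the (normalized)
#' covariance direction `X'y`; each orthogonal component captures
#' within-X variation uncorrelated with the class and is deflated before
#' the single predictive component is fitted. For one response NIPALS
#' needs no iteration loop, so the fit is fully deterministic.
#'
#' @param X Numeric matrix (samples x buckets), column-scaled (e.g. Pareto).
#' @param y Numeric class vector in {-1, +1}; both classes present.
#' @param n_ortho Number of orthogonal components to extract (0..9).
#' @return An `opls_model`: predictive weight `w` (unit norm), loading `p`,
#'   training scores `t`, regression coefficient `b`, orthogonal weights /
#'   loadings / scores (`W_o`, `P_o`, `T_o`), `n_ortho`, `r2y`, fitted
#'   values `fitted`.
#' @export
fit_opls <- function(X, y, n_ortho = 0L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stop_if(length(y) != nrow(X), "length(y) must equal nrow(X)")
  stop_if(stats::var(y) == 0, "y has zero variance (one class only)")
  stop_if(n_ortho < 0 || n_ortho > 9, "n_ortho must be in 0..9")
  J <- ncol(X)

  w <- crossprod(X, y)[, 1]
  nw <- sqrt(sum(w^2))
  stop_if(nw < 1e-12, "no class-correlated signal (||X'y|| below floor)")
  w <- w / nw

  W_o <- matrix(0, J, 0)
  P_o <- matrix(0, J, 0)
  T_o <- matrix(0, nrow(X), 0)
  for (comp in seq_len(n_ortho)) {
    t_pred <- drop(X %*% w)
    p <- crossprod(X, t_pred)[, 1] / sum(t_pred^2)
    w_o <- p - sum(w * p) * w
    n_wo <- sqrt(sum(w_o^2))
    if (n_wo < 1e-12) break  # no orthogonal variation left
    w_o <- w_o / n_wo
    t_o <- drop(X %*% w_o)
    p_o <- crossprod(X, t_o)[, 1] / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
  }

  t_pred <- drop(X %*% w)
  ss_t <- sum(t_pred^2)
  stop_if(ss_t < 1e-24, "predictive score collapsed to zero")
  b <- sum(y * t_pred) / ss_t
  p <- crossprod(X, t_pred)[, 1] / ss_t
  fitted <- t_pred * b
  r2y <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)

  structure(list(w = w, p = p, t = t_pred, b = b,
                 W_o = W_o, P_o = P_o, T_o = T_o,
                 n_ortho = ncol(W_o), r2y = r2y, fitted = fitted,
                 class_coding = c(negative = -1, positive = 1)),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> %d buckets, %d orthogonal component(s), R2Y = %.3f\n",
              length(x$w), x$n_ortho, x$r2y))
  invisible(x)
}

#' Predict OPLS-DA scores for new samples
#'
#' Applies the training orthogonal filters in order, then projects onto the
#' predictive weight and scales by the regression coefficient. New data must
#' be scaled with the training scaling model, never refit.
#'
#' @param model An `opls_model`.
#' @param X_new Numeric matrix with the training bucket count.
#' @return Numeric predicted score per row (threshold 0 separates classes
#'   under the symmetric class coding).
#' @export
predict_scores <- function(model, X_new) {
  stopifnot(inherits(model, "opls_model"))
  X_new <- as.matrix(X_new)
  stop_if(ncol(X_new) != length(model$w),
          "bucket count mismatch: model has %d, data has %d",
          length(model$w), ncol(X_new))
  for (comp in seq_len(model$n_ortho)) {
    t_o <- drop(X_new %*% model$W_o[, comp])
    X_new <- X_new - tcrossprod(t_o, model$P_o[, comp])
  }
  drop(X_new %*% model$w) * model$b
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over k folds. Returns an integer fold id per sample.
stratified_folds <- function(y, k, seed = NULL) {
  with_seed(seed, {
    folds <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

#' Internal cross-validated Q2
#'
#' Q2 = 1 - PRESS/SS with PRESS the squared out-of-fold prediction error
#' summed over stratified folds and SS the total squared deviation of y
#' from its mean. Used to choose the number of orthogonal components.
#'
#' @param X Column-scaled matrix; `y` class vector in {-1, +1}.
#' @param y Class vector.
#' @param n_ortho Orthogonal component count passed to [fit_opls()].
#' @param k Number of folds (default 7).
#' @param seed Seed for the fold assignment.
#' @return Q2 (a real number, at most 1; negative means worse than the mean
#'   predictor).
#' @export
q2_internal_cv <- function(X, y, n_ortho = 0L, k = 7L, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stop_if(n < k, "need at least k samples")
  folds <- valid_folds(y, k, seed)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    hold <- folds == f
    fit <- fit_opls(X[!hold, , drop = FALSE], y[!hold], n_ortho)
    pred[hold] <- predict_scores(fit, X[hold, , drop = FALSE])
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

# Fold assignment where every training fold keeps both classes; refolds
# with a new derived seed on failure, erroring after 100 attempts.
valid_folds <- function(y, k, seed) {
  for (attempt in 0:99) {
    s <- if (is.null(seed)) NULL else child_seed(seed, attempt)
    folds <- stratified_folds(y, k, s)
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y[folds != f])) == 2L
    }, logical(1)))
    if (ok) return(folds)
  }
  stop("could not stratify folds with both classes in every training fold",
       call. = FALSE)
}

# Nested OPLS fits for all depths 0..max_ortho in one deflation pass.
# Components are nested (w is fixed; orthogonal components sequential), so
# this is equivalent to max_ortho + 1 separate fit_opls() calls.
# Returns w, per-depth regression coefficients b, and W_o / P_o.
opls_path <- function(X, y, max_ortho) {
  w <- crossprod(X, y)[, 1]
  nw <- sqrt(sum(w^2))
  stop_if(nw < 1e-12, "no class-correlated signal (||X'y|| below floor)")
  w <- w / nw
  J <- ncol(X)
  b <- numeric(max_ortho + 1)
  W_o <- matrix(0, J, max_ortho)
  P_o <- matrix(0, J, max_ortho)
  depth <- 0L
  for (a in 0:max_ortho) {
    t_pred <- drop(X %*% w)
    b[a + 1] <- sum(y * t_pred) / sum(t_pred^2)
    if (a == max_ortho) break
    p <- crossprod(X, t_pred)[, 1] / sum(t_pred^2)
    w_o <- p - sum(w * p) * w
    n_wo <- sqrt(sum(w_o^2))
    if (n_wo < 1e-12) {        # no orthogonal variation left: deeper
      b[(a + 2):(max_ortho + 1)] <- b[a + 1]  # depths equal this one
      break
    }
    w_o <- w_o / n_wo
    t_o <- drop(X %*% w_o)
    p_o <- crossprod(X, t_o)[, 1] / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    W_o[, a + 1] <- w_o
    P_o[, a + 1] <- p_o
    depth <- a + 1L
  }
  list(w = w, b = b, W_o = W_o, P_o = P_o, depth = depth)
}

# Predicted scores at every depth 0..max_ortho (columns) for new samples.
predict_path <- function(path, X_new, max_ortho) {
  out <- matrix(0, nrow(X_new), max_ortho + 1)
  for (a in 0:max_ortho) {
    out[, a + 1] <- drop(X_new %*% path$w) * path$b[a + 1]
    if (a < path$depth) {
      t_o <- drop(X_new %*% path$W_o[, a + 1])
      X_new <- X_new - tcrossprod(t_o, path$P_o[, a + 1])
    }
  }
  out
}

#' Select the number of orthogonal components by internal CV
#'
#' Evaluates 0..`max_ortho` orthogonal components with seven-fold internal
#' cross-validation (same fold assignment across candidates) and returns
#' the count maximizing Q2, ties broken toward fewer components. The
#' candidates are fitted in one nested deflation pass per fold; the Q2
#' values are identical to calling [q2_internal_cv()] per candidate with
#' the same seed.
#'
#' @param X,y As in [fit_opls()].
#' @param max_ortho Maximum number of orthogonal components (default 9).
#' @param k Internal fold count (default 7).
#' @param seed Fold seed.
#' @return List with `n_ortho` (the argmax) and `q2` (one value per
#'   candidate 0..max_ortho).
#' @export
select_n_orthogonal <- function(X, y, max_ortho = 9L, k = 7L, seed = NULL) {
  X <- as.matrix(X)
  folds <- valid_folds(y, k, seed)
  pred <- matrix(0, nrow(X), max_ortho + 1)
  for (f in seq_len(k)) {
    hold <- folds == f
    path <- opls_path(X[!hold, , drop = FALSE], y[!hold], max_ortho)
    pred[hold, ] <- predict_path(path, X[hold, , drop = FALSE], max_ortho)
  }
  ss <- sum((y - mean(y))^2)
  q2 <- 1 - colSums((y - pred)^2) / ss
  names(q2) <- as.character(0:max_ortho)
  list(n_ortho = unname(which.max(q2)) - 1L, q2 = q2)
}

#' Variable importance in projection (VIP)
#'
#' VIP over the single predictive component: with J buckets and unit-norm
#' predictive weight w, VIP_j = sqrt(J) * |w_j|, so the mean squared VIP is
#' exactly 1. Buckets with VIP > 2 are flagged significant.
#'
#' @param model A fitted `opls_model`.
#' @param cutoff Significance cutoff (default 2).
#' @return A `vip_scores` list: `vip` (per bucket), `significant` (indices
#'   with VIP above the cutoff), `cutoff`.
#' @export
vip <- function(model, cutoff = 2) {
  stopifnot(inherits(model, "opls_model"))
  J <- length(model$w)
  v <- unname(sqrt(J) * abs(model$w))
  # tolerance keeps a score sitting exactly on the cutoff significant
  structure(list(vip = v, significant = which(v > cutoff - 1e-12),
                 cutoff = cutoff),
            class = "vip_scores")
}
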