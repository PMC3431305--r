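#' Principal components analysis of a scaled feature matrix
#'
#' Fits PCA by singular value decomposition of the column-centered matrix
#' (equivalent to an eigendecomposition of the covariance matrix).
#' Component signs are fixed so the loading of largest magnitude in each
#' component is positive.
#'
#' @param X numeric matrix (observations x features), typically the `X`
#'   element of [pareto_scale()]. Centered internally.
#' @param n_components number of components, or `"auto"` to add components
#'   while the cross-validated Q2 gain exceeds `q2_gain`.
#' @param q2_gain minimum Q2 improvement to add a component in auto mode.
#' @param cv_folds,seed fold count and RNG seed for the auto-mode CV.
#' @return object of class `pca_model`: `center`, `loadings` (features x
#'   components), `scores` (observations x components), `r2x_per_component`,
#'   `r2x_cum`, `q2_cum` (`NA` unless auto mode ran CV).
#' @export
fit_pca <- function(X, n_components = 2, q2_gain = 0.01, cv_folds = 7, seed = 1) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  tot <- sum(Xc^2)
  if (tot == 0) stop("degenerate all-zero (constant) matrix")
  max_comp <- min(nrow(X) - 1L, ncol(X))
  q2_cum <- NA_real_
  if (identical(n_components, "auto")) {
    q2s <- numeric(0)
    a <- 0L
    while (a < max_comp) {
      q2 <- pca_q2(Xc, a + 1L, k = cv_folds, seed = seed)
      if (a > 0L && q2 - q2s[a] <= q2_gain) break
      a <- a + 1L
      q2s[a] <- q2
    }
    n_components <- max(a, 1L)
    q2_cum <- q2s[n_components]
  }
  n_components <- min(n_components, max_comp)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  P <- sv$v
  Tm <- sv$u %*% diag(d, n_components)
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(n_components)) {
    s <- sign(P[which.max(abs(P[, j])), j])
    if (s < 0) { P[, j] <- -P[, j]; Tm[, j] <- -Tm[, j] }
  }
  r2 <- d^2 / tot
  structure(list(center = ctr, loadings = P, scores = Tm,
                 r2x_per_component = r2, r2x_cum = sum(r2), q2_cum = q2_cum,
                 n_components = n_components),
            class = "pca_model")
}

# Row-wise k-fold PRESS for PCA with `a` components: held-out rows are
# projected onto loadings fitted without them. Optimistic relative to
# element-wise deletion schemes but adequate as a stopping rule.
pca_q2 <- function(Xc, a, k = 7, seed = 1) {
  n <- nrow(Xc)
  k <- min(k, n)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  press <- 0
  for (f in seq_len(k)) {
    tr <- Xc[fold != f, , drop = FALSE]
    te <- Xc[fold == f, , drop = FALSE]
    tr <- sweep(tr, 2, colMeans(tr))
    aa <- min(a, nrow(tr) - 1L, ncol(tr))
    V <- svd(tr, nu = 0, nv = aa)$v
    resid <- te - te %*% V %*% t(V)
    press <- press + sum(resid^2)
  }
  1 - press / sum(Xc^2)
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components, R2X(cum) = %.1f%%\n",
              x$n_components, 100 * x$r2x_cum))
  invisible(x)
}

#' Hotelling T-squared confidence ellipse for a 2-component score plot
#'
#' Computes the axis-aligned 95% (by default) confidence ellipse used on
#' PCA/OPLS-DA score scatter plots, and flags observations whose T-squared
#' statistic exceeds the critical value.
#'
#' The semi-axis along component i is
#' `s_i * sqrt(2 (n^2 - 1) / (n (n - 2)) * F(1 - alpha; 2, n - 2))`,
#' with `s_i` the component score standard deviation.
#'
#' @param scores two-column score matrix.
#' @param alpha significance level (default 0.05 for a 95% ellipse).
#' @return list: `semi_axes` (length 2), `sd` (component sds), `t2`
#'   (per-observation statistic), `critical`, `outliers` (logical).
#' @export
hotelling_ellipse <- function(scores, alpha = 0.05) {
  Tm <- as.matrix(scores)
  if (ncol(Tm) != 2) stop("scores must have exactly 2 columns")
  n <- nrow(Tm)
  if (n < 3) stop("need at least 3 observations")
  s <- apply(Tm, 2, stats::sd)
  crit <- 2 * (n^2 - 1) / (n * (n - 2)) * stats::qf(1 - alpha, 2, n - 2)
  Tc <- sweep(Tm, 2, colMeans(Tm))
  t2 <- rowSums(sweep(Tc, 2, s, "/")^2)
  list(semi_axes = s * sqrt(crit), sd = s, t2 = t2, critical = crit,
       outliers = t2 > crit)
}
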