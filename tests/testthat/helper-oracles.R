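# Independent oracles used by the tests. These deliberately avoid the
# package's own NIPALS / agglomeration code paths.

# PLS2 by eigendecomposition: the first weight vector is the dominant
# eigenvector of X'Y Y'X; further components by explicit deflation.
# Returns predicted Y for the training data.
pls2_eigen_oracle <- function(X, y, n_comp = 1) {
  y <- droplevels(as.factor(y))
  Y <- stats::model.matrix(~ y - 1)
  ym <- colMeans(Y)
  Yc <- sweep(Y, 2, ym)
  Xc <- sweep(X, 2, colMeans(X))
  Yhat <- matrix(0, nrow(X), ncol(Y))
  for (a in seq_len(n_comp)) {
    M <- crossprod(Xc, Yc)
    ev <- eigen(tcrossprod(M), symmetric = TRUE)
    w <- ev$vectors[, 1]
    t_ <- Xc %*% w
    p_ <- crossprod(Xc, t_) / sum(t_^2)
    c_ <- crossprod(Yc, t_) / sum(t_^2)
    Yhat <- Yhat + tcrossprod(t_, c_)
    Xc <- Xc - tcrossprod(t_, p_)
    Yc <- Yc - tcrossprod(t_, c_)
  }
  sweep(Yhat, 2, ym, "+")
}

# Maximum edge weight of the Euclidean minimum spanning tree (Prim).
mst_bottleneck_oracle <- function(P) {
  D <- as.matrix(stats::dist(P))
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  max_edge <- 0
  for (i in seq_len(n - 1)) {
    j <- which(!in_tree)[which.min(best[!in_tree])]
    max_edge <- max(max_edge, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  max_edge
}

# Small two-class data set with a multiplicative effect on the first
# n_signal features; returns the Pareto-scaled matrix and labels.
make_two_class <- function(n_per = 6, p = 20, n_signal = 4, effect = 4,
                           noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  base <- matrix(stats::rlnorm(2 * n_per * p, 2, 0.3), 2 * n_per, p)
  grp <- rep(c("A", "B"), each = n_per)
  base[grp == "B", seq_len(n_signal)] <-
    base[grp == "B", seq_len(n_signal)] * effect
  X <- base * matrix(1 + noise_sd * stats::rnorm(length(base)),
                     nrow(base), ncol(base))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = pareto_scale(X)$X, y = factor(grp), raw = X)
}

# replicate the package's seeded stratified fold assignment
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
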