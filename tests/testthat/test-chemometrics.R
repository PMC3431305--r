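test_that("PCA recovers rank structure and matches an eigendecomposition oracle", {
  # rank-1 matrix: first component explains everything
  u <- c(1, 2, 3, 4); v <- c(2, -1, 0.5)
  X1 <- outer(u, v)
  m1 <- fit_pca(X1, n_components = 2)
  expect_equal(m1$r2x_per_component[1], 1, tolerance = 1e-12)
  expect_equal(sweep(m1$scores %*% t(m1$loadings), 2, -m1$center), X1,
               tolerance = 1e-10, ignore_attr = TRUE)

  set.seed(7)
  X <- matrix(rnorm(60), 10, 6)
  m <- fit_pca(X, n_components = 6)
  expect_true(all(diff(m$r2x_per_component) <= 1e-12))
  expect_equal(sum(m$r2x_per_component), m$r2x_cum)
  # independent oracle: eigendecomposition of the covariance matrix
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc), symmetric = TRUE)
  for (j in 1:5) {
    expect_equal(abs(m$loadings[, j]), abs(ev$vectors[, j]), tolerance = 1e-8)
    expect_equal(abs(m$scores[, j]), abs(Xc %*% ev$vectors[, j])[, 1],
                 tolerance = 1e-8)
  }
  # scores are mutually orthogonal
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_error(fit_pca(matrix(0, 4, 3)), "degenerate")
})

test_that("Hotelling ellipse scales with the scores and flags the right points", {
  set.seed(45)
  Tm <- matrix(rnorm(90), 45, 2)
  h <- hotelling_ellipse(Tm)
  n <- 45
  crit <- 2 * (n^2 - 1) / (n * (n - 2)) * qf(0.95, 2, n - 2)
  s <- apply(Tm, 2, sd)
  t2 <- rowSums(sweep(sweep(Tm, 2, colMeans(Tm)), 2, s, "/")^2)
  expect_equal(which(h$outliers), which(t2 > crit))
  expect_equal(h$semi_axes, s * sqrt(crit))
  # doubling the scores doubles the semi-axes; equal sds give a circle
  expect_equal(hotelling_ellipse(2 * Tm)$semi_axes, 2 * h$semi_axes)
  Tc <- cbind(Tm[, 1], rev(Tm[, 1]))
  hc <- hotelling_ellipse(Tc)
  expect_equal(hc$semi_axes[1], hc$semi_axes[2])
  expect_error(hotelling_ellipse(Tm[1:2, ]), "3 observations")
})

test_that("OPLS-DA with no orthogonal components equals the PLS2 oracle", {
  d <- make_two_class(n_per = 6, p = 8, seed = 12)
  m <- fit_oplsda(d$X, d$y, n_pred = 1, n_orth = 0)
  y_hat <- predict(m, d$X, n_pred_use = 1)$y_hat
  expect_equal(y_hat, pls2_eigen_oracle(d$X, d$y, 1), tolerance = 1e-8,
               ignore_attr = TRUE)
  # 3-class, 2 predictive components
  set.seed(5)
  X3 <- matrix(rnorm(15 * 8), 15, 8)
  y3 <- factor(rep(c("A", "B", "C"), each = 5))
  X3[y3 == "B", 1] <- X3[y3 == "B", 1] + 3
  X3[y3 == "C", 2] <- X3[y3 == "C", 2] + 3
  m3 <- fit_oplsda(X3, y3, n_pred = 2, n_orth = 0)
  expect_equal(predict(m3, X3)$y_hat, pls2_eigen_oracle(X3, y3, 2),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a perfect predictor dominates the predictive weights", {
  set.seed(2)
  n <- 12
  y <- factor(rep(c("A", "B"), each = n / 2))
  contrast <- ifelse(y == "A", -1, 1)
  X <- cbind(contrast, matrix(0.01 * rnorm(n * 5), n, 5))
  m <- fit_oplsda(X, y, n_pred = 1, n_orth = 0)
  expect_gt(abs(m$weights[1, 1]), 0.99)
  expect_gt(m$r2y_cum, 0.99)
})

test_that("structured class-unrelated variation is absorbed by orthogonal components", {
  set.seed(9)
  n <- 20; p <- 30
  y <- factor(rep(c("A", "B"), each = n / 2))
  contrast <- ifelse(y == "A", -1, 1)
  X0 <- outer(contrast, rnorm(p)) + 0.3 * matrix(rnorm(n * p), n, p)
  # structured component with zero class contrast (same loadings both classes)
  s <- rnorm(n); s <- s - mean(s); s <- s - contrast * sum(s * contrast) / n
  X1 <- X0 + 4 * outer(s, rnorm(p))
  m0 <- fit_oplsda(X0, y, n_pred = 1, n_orth = 0)
  m1 <- fit_oplsda(X1, y, n_pred = 1, n_orth = 1)
  expect_gt(m1$r2x_o, 3 * m0$r2x_o + 0.2)
  expect_gt(abs(cor(m0$scores[, 1], m1$scores[, 1])), 0.99)
})

test_that("predictive/orthogonal variance partition is exact and scores orthogonal", {
  d <- make_two_class(n_per = 8, p = 25, seed = 4)
  m <- fit_oplsda(d$X, d$y, n_pred = 1, n_orth = 2)
  # R2Xp + R2Xo equals the reconstruction-based total explained variance
  Xc <- sweep(d$X, 2, colMeans(d$X))
  recon <- m$scores %*% t(m$loadings) + m$scores_orth %*% t(m$loadings_orth)
  r2_total <- 1 - sum((Xc - recon)^2) / sum(Xc^2)
  expect_equal(m$r2x_p + m$r2x_o, r2_total, tolerance = 1e-8)
  expect_equal(m$r2x_cum, m$r2x_p + m$r2x_o, tolerance = 1e-12)
  # Tp and To orthogonal after normalization
  ip <- abs(crossprod(m$scores / sqrt(sum(m$scores^2)),
                      sweep(m$scores_orth, 2,
                            sqrt(colSums(m$scores_orth^2)), "/")))
  expect_lt(max(ip), 1e-6)
})

test_that("cross-validation separates signal from permutation null", {
  d <- make_two_class(n_per = 7, p = 30, n_signal = 10, effect = 6,
                      noise_sd = 0.02, seed = 21)
  cv <- cross_validate(d$X, d$y, k = 7, seed = 1, n_pred = 1)
  expect_gt(cv$q2_cum, 0.9)
  expect_lte(cv$q2_cum, 1)
  # permuted labels: Q2 collapses (seed-fixed permutations)
  set.seed(99)
  q2_null <- replicate(20, {
    yp <- sample(d$y)
    cross_validate(d$X, yp, k = 2, seed = 1, n_pred = 1)$q2_cum
  })
  expect_lt(mean(q2_null), 0.2)
  # guards
  expect_error(cross_validate(d$X, d$y, k = 10, seed = 1), "smallest class")
  y1 <- d$y; y1[1] <- "B"; y1 <- droplevels(factor(c(as.character(y1), "C"),
                                                   levels = c("A", "B", "C")))
  expect_error(cross_validate(rbind(d$X, 0), y1, k = 2, seed = 1),
               "single member")
})

test_that("k = n cross-validation matches a brute-force leave-one-out oracle", {
  d <- make_two_class(n_per = 4, p = 6, seed = 31)
  n <- nrow(d$X)
  cv <- cross_validate(d$X, d$y, k = n, seed = 1, n_pred = 1)
  Y <- stats::model.matrix(~ d$y - 1)
  press <- 0
  for (i in seq_len(n)) {
    m <- fit_oplsda(d$X[-i, ], d$y[-i], n_pred = 1, n_orth = 0)
    y_hat <- predict(m, d$X[i, , drop = FALSE])$y_hat
    press <- press + sum((Y[i, ] - y_hat)^2)
  }
  ss <- sum(sweep(Y, 2, colMeans(Y))^2)
  expect_equal(cv$q2_cum, 1 - press / ss, tolerance = 1e-12)
})

test_that("classification is consistent on separated data and symmetric at the centroid", {
  d <- make_two_class(n_per = 6, p = 12, effect = 8, noise_sd = 0.05,
                      seed = 17)
  m <- fit_oplsda(d$X, d$y, n_pred = 1, n_orth = 0)
  cl <- classify(m, d$X)
  expect_equal(as.character(cl$predicted), as.character(d$y))
  # the grand centroid of balanced classes predicts equal class scores
  centroid <- matrix(colMeans(d$X), 1)
  expect_warning(pc <- classify(m, centroid), "tied")
  expect_equal(pc$A, pc$B, tolerance = 1e-10)
  expect_error(predict(m, d$X[, 1:5]), "feature mismatch")
})

test_that("misclassification tables count errors and reject unseen labels", {
  t1 <- misclassification_table(c("A", "A", "B"), c("A", "A", "B"))
  expect_equal(t1$accuracy, 1)
  expect_equal(diag(t1$counts), c(A = 2L, B = 1L))
  t2 <- misclassification_table(rep(c("A", "B"), c(3, 2)), rep("A", 5))
  expect_equal(sum(t2$counts[, "B"]), 0L)
  true <- rep(c("A", "B", "C"), c(20, 15, 10))
  pred <- true; pred[1:10] <- c(rep("B", 5), rep("C", 5))
  t3 <- misclassification_table(true, pred)
  expect_equal(t3$accuracy, 35 / 45)
  expect_equal(t3$n_misclassified, 10L)
  expect_error(misclassification_table(c("A", "B"), c("A", "Z")), "Z")
})

test_that("Fisher point probability matches enumeration and is relabel-invariant", {
  # margins (2,2)/(2,2): three tables with probabilities 1/6, 4/6, 1/6
  expect_equal(fisher_exact_probability(matrix(c(2, 0, 0, 2), 2)), 1 / 6)
  expect_equal(fisher_exact_probability(matrix(c(1, 1, 1, 1), 2)), 4 / 6)
  expect_equal(fisher_exact_probability(matrix(5, 1, 1)), 1)
  m <- matrix(c(6, 1, 0, 2, 20, 3, 1, 2, 10), 3)
  perm <- c(3, 1, 2)
  expect_equal(fisher_exact_probability(m),
               fisher_exact_probability(m[perm, perm]))
  expect_error(fisher_exact_probability(matrix(c(1.5, 0, 0, 1), 2)),
               "integer")
})
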