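#' @title Multi-class OPLS-DA
#' @description
#' Orthogonal projections to latent structures discriminant analysis.
#' Class membership is dummy-coded (one centered indicator column per
#' class); variation in X is partitioned into components predictive of
#' class and components orthogonal to it. Orthogonal components are
#' extracted and deflated first, then predictive components are fitted on
#' the filtered matrix by NIPALS PLS2 — so with `n_orth = 0` the model is
#' exactly a PLS2 discriminant model.
#'
#' For each orthogonal component the first NIPALS PLS component of the
#' current matrix gives a loading `p`; the part of `p` lying in the span of
#' the class-predictive weight directions (the columns of `X'Y`) is removed,
#' the remainder is normalized into an orthogonal weight `w_o`, and the
#' corresponding score/loading pair is deflated from X.
#'
#' @param X numeric matrix (observations x features), Pareto-scaled (any
#'   remaining column means are removed internally).
#' @param y class labels (factor or character), >= 2 classes with >= 2
#'   members each.
#' @param n_pred number of predictive components (at most K-1 for K
#'   classes; default K-1), or `"auto"`.
#' @param n_orth number of orthogonal components (default 0), or `"auto"`.
#'   Auto mode adds a component while the 7-fold cross-validated Q2Y(cum)
#'   improves by more than `q2_gain`.
#' @param q2_gain minimum Q2 improvement for auto component selection.
#' @param cv_folds,seed folds and RNG seed used by auto selection.
#' @return object of class `oplsda_model` with elements: `class_levels`;
#'   predictive `weights`, `loadings`, `scores`, `y_loadings`; orthogonal
#'   `weights_orth`, `loadings_orth`, `scores_orth`; centering vectors;
#'   and fit statistics `r2x_p`, `r2x_o`, `r2x_cum`, `r2y_cum`
#'   (`q2y_cum` is filled in by [cross_validate()]).
#' @seealso [classify()], [cross_validate()], [splot()]
#' @export
fit_oplsda <- function(X, y, n_pred = NULL, n_orth = 0, q2_gain = 0.01,
                       cv_folds = 7, seed = 1) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  if (K < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 members")
  if (nrow(X) != length(y)) stop("X rows do not match y length")
  if (is.null(n_pred)) n_pred <- K - 1L

  if (identical(n_orth, "auto") || identical(n_pred, "auto")) {
    return(auto_oplsda(X, y, n_pred, n_orth, q2_gain, cv_folds, seed))
  }
  n_pred <- as.integer(n_pred)
  n_orth <- as.integer(n_orth)
  if (n_pred > K - 1L)
    stop("at most K-1 = ", K - 1L, " predictive components for ", K, " classes")

  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  tot_x <- sum(Xc^2)
  if (tot_x == 0) stop("degenerate all-zero (constant) matrix")
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means)
  tot_y <- sum(Yc^2)

  # -- orthogonal components -------------------------------------------------
  Wo <- Po <- To <- NULL
  Xf <- Xc
  for (j in seq_len(n_orth)) {
    cmp <- nipals_pls_component(Xf, Yc)
    # orthonormal basis of the predictive-weight subspace of the current X
    WY <- crossprod(Xf, Yc)
    sv <- svd(WY)
    rank <- sum(sv$d > max(sv$d[1], 1) * 1e-10)
    U <- sv$u[, seq_len(rank), drop = FALSE]
    w_o <- cmp$p - U %*% crossprod(U, cmp$p)
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12 * sqrt(sum(cmp$p^2)) || !is.finite(nrm) || nrm == 0)
      stop("no orthogonal variation left after ", j - 1L, " component(s)")
    w_o <- w_o / nrm
    t_o <- Xf %*% w_o
    p_o <- crossprod(Xf, t_o) / sum(t_o^2)
    Xf <- Xf - tcrossprod(t_o, p_o)
    Wo <- cbind(Wo, w_o); Po <- cbind(Po, p_o); To <- cbind(To, t_o)
  }

  # -- predictive components on the filtered matrix (NIPALS PLS2) ------------
  Wp <- Pp <- Tp <- Cp <- NULL
  Xd <- Xf; Yd <- Yc
  for (a in seq_len(n_pred)) {
    cmp <- nipals_pls_component(Xd, Yd)
    Xd <- Xd - tcrossprod(cmp$t, cmp$p)
    Yd <- Yd - tcrossprod(cmp$t, cmp$c)
    Wp <- cbind(Wp, cmp$w); Pp <- cbind(Pp, cmp$p)
    Tp <- cbind(Tp, cmp$t); Cp <- cbind(Cp, cmp$c)
  }

  # sign convention: largest-|loading| entry positive, applied jointly
  for (a in seq_len(n_pred)) {
    if (Pp[which.max(abs(Pp[, a])), a] < 0) {
      Pp[, a] <- -Pp[, a]; Wp[, a] <- -Wp[, a]
      Tp[, a] <- -Tp[, a]; Cp[, a] <- -Cp[, a]
    }
  }
  for (j in seq_len(n_orth)) {
    if (Po[which.max(abs(Po[, j])), j] < 0) {
      Po[, j] <- -Po[, j]; Wo[, j] <- -Wo[, j]; To[, j] <- -To[, j]
    }
  }

  r2x_p_per <- if (n_pred) colSums(Tp^2) * colSums(Pp^2) / tot_x else numeric(0)
  r2x_o_per <- if (n_orth) colSums(To^2) * colSums(Po^2) / tot_x else numeric(0)
  r2y_cum <- 1 - sum(Yd^2) / tot_y

  structure(list(
    class_levels = levels(y), y = y,
    x_center = x_center, y_means = y_means,
    weights = Wp, loadings = Pp, scores = Tp, y_loadings = Cp,
    weights_orth = Wo, loadings_orth = Po, scores_orth = To,
    n_pred = n_pred, n_orth = n_orth,
    r2x_p = sum(r2x_p_per), r2x_o = sum(r2x_o_per),
    r2x_p_per_component = r2x_p_per, r2x_o_per_component = r2x_o_per,
    r2x_cum = sum(r2x_p_per) + sum(r2x_o_per),
    r2y_cum = r2y_cum, q2y_cum = NA_real_),
    class = "oplsda_model")
}

# One NIPALS PLS component of (X, Y), both centered.
nipals_pls_component <- function(X, Y, tol = 1e-14, maxit = 1000) {
  u <- Y[, which.max(colSums(Y^2))]
  if (sum(u^2) == 0) u <- Y[, 1] + 1e-12
  t_old <- NULL
  for (it in seq_len(maxit)) {
    w <- crossprod(X, u)
    w <- w / sqrt(sum(w^2))
    t <- X %*% w
    cc <- crossprod(Y, t) / sum(t^2)
    u <- Y %*% cc / sum(cc^2)
    if (!is.null(t_old) && sum((t - t_old)^2) <= tol * sum(t^2)) break
    t_old <- t
  }
  p <- crossprod(X, t) / sum(t^2)
  list(w = drop(w), t = drop(t), p = drop(p), c = drop(cc))
}

auto_oplsda <- function(X, y, n_pred, n_orth, q2_gain, cv_folds, seed) {
  K <- nlevels(droplevels(as.factor(y)))
  pred_fixed <- if (identical(n_pred, "auto")) K - 1L else as.integer(n_pred)
  if (identical(n_orth, "auto")) {
    best <- 0L
    q2_best <- cross_validate(X, y, k = cv_folds, seed = seed,
                              n_pred = pred_fixed, n_orth = 0L)$q2_cum
    for (j in seq_len(10L)) {
      q2 <- tryCatch(
        cross_validate(X, y, k = cv_folds, seed = seed,
                       n_pred = pred_fixed, n_orth = j)$q2_cum,
        error = function(e) -Inf)
      if (q2 - q2_best > q2_gain) { best <- j; q2_best <- q2 } else break
    }
    n_orth <- best
  }
  if (identical(n_pred, "auto")) {
    best <- 1L
    q2_best <- cross_validate(X, y, k = cv_folds, seed = seed,
                              n_pred = 1L, n_orth = n_orth)$q2_cum
    for (a in seq_len(K - 1L)[-1]) {
      q2 <- cross_validate(X, y, k = cv_folds, seed = seed,
                           n_pred = a, n_orth = n_orth)$q2_cum
      if (q2 - q2_best > q2_gain) { best <- a; q2_best <- q2 } else break
    }
    n_pred <- best
  }
  m <- fit_oplsda(X, y, n_pred = n_pred, n_orth = n_orth)
  m$q2y_cum <- cross_validate(X, y, k = cv_folds, seed = seed,
                              n_pred = n_pred, n_orth = n_orth)$q2_cum
  m
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf(
    "oplsda_model: %d class(es) [%s], %d predictive + %d orthogonal component(s)\n",
    length(x$class_levels), paste(x$class_levels, collapse = ", "),
    x$n_pred, x$n_orth))
  cat(sprintf("  R2Xp = %.1f%%, R2Xo = %.1f%%, R2X(cum) = %.1f%%, R2Y(cum) = %.1f%%",
              100 * x$r2x_p, 100 * x$r2x_o, 100 * x$r2x_cum, 100 * x$r2y_cum))
  if (!is.na(x$q2y_cum)) cat(sprintf(", Q2Y(cum) = %.1f%%", 100 * x$q2y_cum))
  cat("\n")
  invisible(x)
}

#' Project new observations through an OPLS-DA model
#'
#' Removes the model's orthogonal components from the new data, computes
#' predictive scores, and predicts the dummy class indicators.
#'
#' @param object an `oplsda_model`.
#' @param newdata matrix scaled with the training scaling parameters
#'   (see [pareto_apply()]).
#' @param n_pred_use use only the first so-many predictive components
#'   (default: all).
#' @param ... unused.
#' @return list: `scores` (predictive), `scores_orth`, `y_hat`
#'   (observations x classes).
#' @export
predict.oplsda_model <- function(object, newdata, n_pred_use = object$n_pred, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_center))
    stop("feature mismatch: new data has ", ncol(X),
         " columns, model was trained on ", length(object$x_center))
  Xc <- sweep(X, 2, object$x_center)
  To_new <- NULL
  for (j in seq_len(object$n_orth)) {
    t_o <- Xc %*% object$weights_orth[, j, drop = FALSE]
    Xc <- Xc - t_o %*% t(object$loadings_orth[, j, drop = FALSE])
    To_new <- cbind(To_new, t_o)
  }
  Tp_new <- matrix(0, nrow(X), object$n_pred)
  for (a in seq_len(object$n_pred)) {
    t_a <- Xc %*% object$weights[, a, drop = FALSE]
    Xc <- Xc - t_a %*% t(object$loadings[, a, drop = FALSE])
    Tp_new[, a] <- t_a
  }
  use <- seq_len(n_pred_use)
  y_hat <- Tp_new[, use, drop = FALSE] %*%
    t(object$y_loadings[, use, drop = FALSE])
  y_hat <- sweep(y_hat, 2, object$y_means, "+")
  colnames(y_hat) <- object$class_levels
  list(scores = Tp_new, scores_orth = To_new, y_hat = y_hat)
}

#' Classify observations with a fitted OPLS-DA model
#'
#' The predicted dummy indicator vector is mapped to per-class scores by a
#' softmax (a monotone surrogate for a modeled class-membership
#' probability); the predicted class is the argmax. Exact ties are broken
#' by class order, with a warning.
#'
#' @param model an `oplsda_model`.
#' @param newdata scaled matrix (training scaling parameters).
#' @return data.frame: `predicted` (factor) plus one probability column per
#'   class.
#' @export
classify <- function(model, newdata) {
  stopifnot(inherits(model, "oplsda_model"))
  y_hat <- predict(model, newdata)$y_hat
  ex <- exp(y_hat - apply(y_hat, 1, max))
  probs <- ex / rowSums(ex)
  pred_i <- apply(probs, 1, which.max)
  ties <- apply(probs, 1, function(p) sum(p == max(p)) > 1)
  if (any(ties))
    warning(sum(ties), " observation(s) tied; broken by class order")
  out <- data.frame(predicted = factor(model$class_levels[pred_i],
                                       levels = model$class_levels))
  cbind(out, as.data.frame(probs))
}

#' Stratified k-fold cross-validation of an OPLS-DA model
#'
#' Folds are stratified by class and assigned by seeded shuffle, so every
#' class appears in every training split. `Q2Y(cum) = 1 - PRESS / SS`, with
#' PRESS summed over held-out dummy-indicator predictions and SS the total
#' centered sum of squares of the dummy matrix. Per-component Q2 values use
#' the first `a` predictive components with the orthogonal filter fixed.
#'
#' @param X scaled matrix; `y` class labels.
#' @param y class labels.
#' @param k number of folds (default 7); must not exceed the smallest
#'   class size, except `k = n` which performs leave-one-out.
#' @param seed RNG seed for fold assignment (required, logged in result).
#' @param n_pred,n_orth component counts passed to [fit_oplsda()].
#' @return object of class `cv_result`: `n_folds`, `press_per_component`,
#'   `ss_y`, `q2_per_component`, `q2_cum`, `fold_assignment`, `seed`.
#' @export
cross_validate <- function(X, y, k = 7, seed = 1, n_pred = NULL, n_orth = 0) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  if (is.null(n_pred)) n_pred <- K - 1L
  sizes <- table(y)
  if (any(sizes < 2))
    stop("class(es) with a single member cannot be cross-validated; ",
         "merge classes or reduce folds")
  if (k == length(y)) {
    fold <- seq_along(y)  # leave-one-out
  } else if (k > min(sizes)) {
    stop("k = ", k, " exceeds the smallest class size (", min(sizes),
         "); reduce folds (or use k = n for leave-one-out)")
  } else {
    set.seed(seed)
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  }
  Y <- stats::model.matrix(~ y - 1)
  ss_y <- sum(sweep(Y, 2, colMeans(Y))^2)
  press <- numeric(n_pred)
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- fit_oplsda(X[tr, , drop = FALSE], y[tr],
                    n_pred = n_pred, n_orth = n_orth)
    for (a in seq_len(n_pred)) {
      y_hat <- predict(m, X[!tr, , drop = FALSE], n_pred_use = a)$y_hat
      press[a] <- press[a] + sum((Y[!tr, , drop = FALSE] - y_hat)^2)
    }
  }
  q2 <- 1 - press / ss_y
  structure(list(n_folds = k, press_per_component = press, ss_y = ss_y,
                 q2_per_component = q2, q2_cum = q2[n_pred],
                 fold_assignment = fold, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d folds (seed %d), Q2Y(cum) = %.3f\n",
              x$n_folds, x$seed, x$q2_cum))
  invisible(x)
}

#' Misclassification (confusion) table
#'
#' @param true true class labels.
#' @param pred predicted class labels; every predicted label must occur in
#'   the true label set.
#' @return list of class `confusion_table`: `counts` (K x K matrix, rows =
#'   true), `class_levels`, `accuracy`, `n_misclassified`.
#' @export
misclassification_table <- function(true, pred) {
  true <- as.character(true); pred <- as.character(pred)
  if (length(true) != length(pred)) stop("label vectors differ in length")
  lev <- sort(unique(true))
  unseen <- setdiff(unique(pred), lev)
  if (length(unseen))
    stop("predicted label(s) absent from true labels: ",
         paste(unseen, collapse = ", "))
  counts <- table(factor(true, lev), factor(pred, lev))
  counts <- matrix(as.integer(counts), nrow = length(lev),
                   dimnames = list(true = lev, predicted = lev))
  acc <- sum(diag(counts)) / sum(counts)
  structure(list(counts = counts, class_levels = lev, accuracy = acc,
                 n_misclassified = sum(counts) - sum(diag(counts))),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  print(x$counts)
  cat(sprintf("accuracy: %.1f%% (%d misclassified)\n",
              100 * x$accuracy, x$n_misclassified))
  invisible(x)
}

#' Fisher exact point probability of a contingency table
#'
#' The generalized hypergeometric point probability of observing exactly
#' the given table with its margins fixed:
#' `P = (prod r_i!) (prod c_j!) / (N! prod n_ij!)`,
#' computed in log-space via `lgamma` so large tables do not overflow.
#' This is the probability of the observed table itself, not a tail sum.
#'
#' @param table a `confusion_table` or nonnegative integer matrix.
#' @return the point probability (a single number in (0, 1]).
#' @export
fisher_exact_probability <- function(table) {
  m <- if (inherits(table, "confusion_table")) table$counts else as.matrix(table)
  if (any(m < 0) || any(m != round(m))) stop("table must be nonnegative integers")
  N <- sum(m)
  if (N < 1) stop("table total must be >= 1")
  lf <- function(x) lgamma(x + 1)
  exp(sum(lf(rowSums(m))) + sum(lf(colSums(m))) - lf(N) - sum(lf(m)))
}
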