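#' S-plot of an OPLS-DA model
#'
#' For each feature, the modeled covariance and modeled correlation of the
#' (Pareto-scaled) feature column with the first predictive score vector:
#' `cov_i = t1' x_i / (n - 1)` and `pcorr_i = cov_i / (s_t1 * s_xi)`, using
#' sample (n-1) standard deviations. Plotted against each other these form
#' the S-shaped cloud whose tails hold candidate biomarkers: covariance is
#' the magnitude axis, correlation the reliability axis. Zero-variance
#' features get `pcorr = 0` and are flagged.
#'
#' @param t1 first predictive score vector, or an `oplsda_model` (its first
#'   predictive score column is used).
#' @param X scaled matrix used to fit the model.
#' @return data.frame of class `splot_points`: `feature_id` (from column
#'   names, else `V1..`), `cov`, `pcorr`, `zero_variance`.
#' @export
splot <- function(t1, X) {
  if (inherits(t1, "oplsda_model")) t1 <- t1$scores[, 1]
  t1 <- as.numeric(t1)
  X <- as.matrix(X)
  if (length(t1) != nrow(X)) stop("t1 length must equal nrow(X)")
  n <- length(t1)
  if (n < 3) stop("need at least 3 observations")
  s_t <- stats::sd(t1)
  if (s_t == 0) stop("constant score vector")
  tc <- t1 - mean(t1)
  Xc <- sweep(X, 2, colMeans(X))
  cv <- drop(crossprod(Xc, tc)) / (n - 1)
  s_x <- apply(X, 2, stats::sd)
  zero <- s_x == 0
  pc <- numeric(ncol(X))
  pc[!zero] <- cv[!zero] / (s_t * s_x[!zero])
  pc <- pmin(1, pmax(-1, pc))
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(X)))
  structure(data.frame(feature_id = ids, cov = cv, pcorr = pc,
                       zero_variance = zero, stringsAsFactors = FALSE),
            class = c("splot_points", "data.frame"))
}

#' Jack-knifed confidence intervals on first-component covariance
#'
#' Reliability assessment of S-plot covariances by a delete-a-fold
#' (grouped) jackknife over the cross-validation segments: the OPLS-DA
#' model is refitted with each fold's observations removed, each refit's
#' first predictive score is sign-aligned to the full model (negated when
#' its correlation with the full-model score on the retained observations
#' is negative), and each feature's covariance with that score is
#' recomputed. The interval is
#' `cov_full +/- t(1 - alpha/2, k - 1) * SE_jack`, with the jackknife
#' standard error `sqrt((k - 1)/k * sum((theta_f - theta_bar)^2))`.
#' A feature is `significant` when its interval excludes 0.
#'
#' @param X scaled matrix; `y` class labels.
#' @param y class labels.
#' @param k folds (default 7), `alpha` level (default 0.05), `seed` for the
#'   stratified fold assignment.
#' @param alpha significance level of the interval.
#' @param seed RNG seed for fold assignment.
#' @param n_pred,n_orth component counts for the refits (defaults as in
#'   [fit_oplsda()]).
#' @return data.frame of class `jackknife_intervals`: `feature_id`,
#'   `cov_estimate`, `se`, `lo`, `hi`, `significant`.
#' @export
jackknife_cov_ci <- function(X, y, k = 7, alpha = 0.05, seed = 1,
                             n_pred = NULL, n_orth = 0) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  sizes <- table(y)
  if (k > min(sizes)) stop("k exceeds the smallest class size; reduce folds")
  full <- fit_oplsda(X, y, n_pred = n_pred, n_orth = n_orth)
  t1_full <- full$scores[, 1]
  sp_full <- splot(t1_full, X)
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  est <- matrix(NA_real_, k, ncol(X))
  for (f in seq_len(k)) {
    keep <- fold != f
    m <- fit_oplsda(X[keep, , drop = FALSE], y[keep],
                    n_pred = n_pred, n_orth = n_orth)
    t1 <- m$scores[, 1]
    al <- stats::cor(t1, t1_full[keep])
    if (!is.finite(al) || abs(al) < 1e-8)
      stop("sign alignment failed for fold ", f,
           ": refit score orthogonal to full-model score")
    if (al < 0) t1 <- -t1
    est[f, ] <- splot(t1, X[keep, , drop = FALSE])$cov
  }
  bar <- colMeans(est)
  se <- sqrt((k - 1) / k * colSums(sweep(est, 2, bar)^2))
  tcrit <- stats::qt(1 - alpha / 2, df = k - 1)
  lo <- sp_full$cov - tcrit * se
  hi <- sp_full$cov + tcrit * se
  structure(data.frame(feature_id = sp_full$feature_id,
                       cov_estimate = sp_full$cov, se = se, lo = lo, hi = hi,
                       significant = lo > 0 | hi < 0,
                       stringsAsFactors = FALSE),
            class = c("jackknife_intervals", "data.frame"))
}

#' Select discriminatory ions from an S-plot
#'
#' A reproducible surrogate for visual tail-picking on the S-plot: a
#' feature is selected when its magnitude and reliability both clear a
#' threshold (`|cov| >= min_abs_cov` and `|pcorr| >= min_abs_pcorr`) and
#' its jack-knifed confidence interval excludes 0. Thresholds default to
#' the 95th percentile of the respective absolute values, i.e. the top 5%
#' tails of the cloud. The result is sorted ascending by covariance, so
#' ions elevated in the positive-scoring class appear last.
#'
#' @param points `splot_points` from [splot()].
#' @param intervals `jackknife_intervals` from [jackknife_cov_ci()],
#'   matched by `feature_id`.
#' @param min_abs_cov,min_abs_pcorr nonnegative thresholds; `NULL` means
#'   the 95th percentile of `|cov|` / `|pcorr|`.
#' @return data.frame: `feature_id`, `cov`, `pcorr`, `lo`, `hi`, sorted by
#'   `cov` ascending.
#' @export
select_discriminatory <- function(points, intervals,
                                  min_abs_cov = NULL, min_abs_pcorr = NULL) {
  if (is.null(min_abs_cov))
    min_abs_cov <- stats::quantile(abs(points$cov), 0.95, names = FALSE)
  if (is.null(min_abs_pcorr))
    min_abs_pcorr <- stats::quantile(abs(points$pcorr), 0.95, names = FALSE)
  if (min_abs_cov < 0 || min_abs_pcorr < 0) stop("thresholds must be >= 0")
  i <- match(points$feature_id, intervals$feature_id)
  if (anyNA(i)) stop("intervals lack feature(s): ",
                     paste(utils::head(points$feature_id[is.na(i)], 5),
                           collapse = ", "))
  sel <- abs(points$cov) >= min_abs_cov &
    abs(points$pcorr) >= min_abs_pcorr &
    intervals$significant[i]
  out <- data.frame(feature_id = points$feature_id[sel],
                    cov = points$cov[sel], pcorr = points$pcorr[sel],
                    lo = intervals$lo[i][sel], hi = intervals$hi[i][sel],
                    stringsAsFactors = FALSE)
  out[order(out$cov), , drop = FALSE]
}
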