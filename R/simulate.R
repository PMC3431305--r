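#' Simulation configuration for synthetic feature tables
#'
#' Defaults emulate the structure of the wheat study: 45 biological lines
#' in 3 market classes (DW 6, HBW 27, SBW 12) with the bread-wheat
#' subclasses (HRS 9, HRW 8, HWW 6, HWS 4; SWW 6, SRW 4, SWS 2), 9
#' technical replicates per line (405 rows), and 3727 features of which
#' most are noise: `n_noise` features are absent line-by-line with
#' probability `dropout` (so the class-wise 80%-presence rule removes them
#' in expectation) and `n_lowmean` features sit below the mean-intensity
#' cutoff. Marker features carry a multiplicative class effect.
#'
#' @param classes named list: class label -> character vector of line ids
#'   (or an integer count, in which case ids are generated). Default: the
#'   45-line wheat design.
#' @param subclasses named character vector line id -> subclass label, or
#'   `NULL` to use the default design's subclasses.
#' @param replicates technical replicates per line (default 9).
#' @param n_features total features (default 3727).
#' @param n_markers number of planted marker features (default 10).
#' @param marker_groups list of class-label vectors; marker j is elevated
#'   in the classes of element `(j - 1) %% length + 1`. Default alternates
#'   durum (`"DW"`) and the pooled bread-wheat classes
#'   (`c("HBW", "SBW")`), the study's primary contrast.
#' @param effect multiplicative intensity shift of a marker in its
#'   elevated class(es) (default 3).
#' @param subclass_effect weaker nested shift planted on
#'   `n_subclass_markers` features for one subclass per class (default
#'   1.5).
#' @param n_subclass_markers features per planted subclass contrast
#'   (default 5).
#' @param n_noise features subject to line-level dropout (default 2420).
#' @param n_lowmean features scaled below the intensity cutoff
#'   (default 437).
#' @param dropout probability a noise feature is absent in a given line
#'   (default 0.6).
#' @param base_meanlog,base_sdlog log-normal location/scale of feature
#'   base intensities (defaults 3 and 1; LC-MS peak areas are
#'   right-skewed).
#' @param bio_sdlog line-level biological log-sd (default 0.3).
#' @param noise_cv technical replicate coefficient of variation
#'   (default 0.2).
#' @param lowmean_max upper bound of the uniform mean assigned to
#'   low-mean features (default 0.8, below the 1.0 cutoff).
#' @param rt_range,mz_range ranges for simulated feature metadata
#'   (defaults 0-35 min and 50-1500 Da).
#' @param seed mandatory RNG seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(classes = NULL, subclasses = NULL,
                              replicates = 9, n_features = 3727,
                              n_markers = 10, marker_groups = NULL,
                              effect = 3, subclass_effect = 1.5,
                              n_subclass_markers = 5,
                              n_noise = 2420, n_lowmean = 437,
                              dropout = 0.6, base_meanlog = 3,
                              base_sdlog = 1, bio_sdlog = 0.3,
                              noise_cv = 0.2, lowmean_max = 0.8,
                              rt_range = c(0, 35), mz_range = c(50, 1500),
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(classes)) {
    sub_sizes <- list(
      DW = c(DW = 6),
      HBW = c(HRS = 9, HRW = 8, HWW = 6, HWS = 4),
      SBW = c(SWW = 6, SRW = 4, SWS = 2))
    classes <- list(); subclasses <- character(0)
    for (cl in names(sub_sizes)) {
      ids <- character(0)
      for (sc in names(sub_sizes[[cl]])) {
        new_ids <- sprintf("%s_%s_%02d", cl, sc, seq_len(sub_sizes[[cl]][[sc]]))
        ids <- c(ids, new_ids)
        subclasses[new_ids] <- sc
      }
      classes[[cl]] <- ids
    }
  } else {
    classes <- lapply(stats::setNames(classes, names(classes)), function(x) {
      if (is.numeric(x)) sprintf("line%02d", seq_len(x)) else as.character(x)
    })
    nms <- names(classes)
    for (cl in nms)
      classes[[cl]] <- paste0(cl, "_", classes[[cl]])
    if (is.null(subclasses)) {
      subclasses <- stats::setNames(
        rep(nms, vapply(classes, length, 1L)), unlist(classes))
    }
  }
  if (any(vapply(classes, length, 1L) < 2)) stop("class sizes must be >= 2")
  stopifnot(dropout >= 0, dropout <= 1, effect > 0, noise_cv >= 0,
            n_noise + n_lowmean + n_markers <= n_features)
  structure(list(classes = classes, subclasses = subclasses,
                 replicates = replicates, n_features = n_features,
                 n_markers = n_markers,
                 marker_groups = if (is.null(marker_groups))
                   list("DW", c("HBW", "SBW")) else marker_groups,
                 effect = effect, subclass_effect = subclass_effect,
                 n_subclass_markers = n_subclass_markers,
                 n_noise = n_noise, n_lowmean = n_lowmean, dropout = dropout,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 bio_sdlog = bio_sdlog, noise_cv = noise_cv,
                 lowmean_max = lowmean_max, rt_range = rt_range,
                 mz_range = mz_range, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a feature table with planted ground truth
#'
#' Line-level true abundances are drawn log-normally per feature; marker
#' features are multiplied by the effect size in their elevated class(es);
#' replicate intensities are the line abundance perturbed by multiplicative
#' Gaussian noise (`1 + noise_cv * z`, floored at 0); noise features are
#' zeroed line-by-line with the dropout probability; low-mean features are
#' rescaled below the intensity cutoff. Deterministic for a fixed seed.
#'
#' @param cfg a [simulation_config()].
#' @return list: `table` (a [feature_table()], `n_lines * replicates` rows)
#'   and `truth` (list with `marker_ids`, `marker_direction` — the elevated
#'   class label(s) per marker, comma-joined —, `noise_ids`, `lowmean_ids`,
#'   `subclass_marker_ids`).
#' @export
simulate_feature_table <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  classes <- cfg$classes
  line_ids <- unlist(classes, use.names = FALSE)
  line_class <- rep(names(classes), vapply(classes, length, 1L))
  n_lines <- length(line_ids)
  p <- cfg$n_features

  rt <- stats::runif(p, cfg$rt_range[1], cfg$rt_range[2])
  mz <- stats::runif(p, cfg$mz_range[1], cfg$mz_range[2])
  ids <- make.unique(format_feature_id(rt, mz))
  roles <- rep("clean", p)
  roles[seq_len(cfg$n_markers)] <- "marker"
  roles[cfg$n_markers + seq_len(cfg$n_noise)] <- "noise"
  roles[cfg$n_markers + cfg$n_noise + seq_len(cfg$n_lowmean)] <- "lowmean"

  base <- stats::rlnorm(p, cfg$base_meanlog, cfg$base_sdlog)
  base[roles == "lowmean"] <- stats::runif(cfg$n_lowmean, 0.05, cfg$lowmean_max)

  # line-level abundances
  A <- outer(rep(1, n_lines), base) *
    matrix(stats::rlnorm(n_lines * p, 0, cfg$bio_sdlog), n_lines, p)

  marker_dir <- character(cfg$n_markers)
  g <- length(cfg$marker_groups)
  for (j in seq_len(cfg$n_markers)) {
    up_classes <- cfg$marker_groups[[(j - 1L) %% g + 1L]]
    marker_dir[j] <- paste(up_classes, collapse = ",")
    A[line_class %in% up_classes, j] <- A[line_class %in% up_classes, j] * cfg$effect
  }

  # weaker nested subclass effect: first subclass of each multi-subclass class
  sub_of_line <- cfg$subclasses[line_ids]
  sub_marker_ids <- character(0)
  clean_idx <- which(roles == "clean")
  take <- 0L
  for (cl in names(classes)) {
    subs <- unique(sub_of_line[line_class == cl])
    if (length(subs) < 2) next
    idx <- clean_idx[take + seq_len(cfg$n_subclass_markers)]
    idx <- idx[!is.na(idx)]
    take <- take + length(idx)
    A[line_class == cl & sub_of_line == subs[1], idx] <-
      A[line_class == cl & sub_of_line == subs[1], idx] * cfg$subclass_effect
    sub_marker_ids <- c(sub_marker_ids, ids[idx])
  }

  # line-level dropout of noise features
  noise_idx <- which(roles == "noise")
  drop <- matrix(stats::runif(n_lines * length(noise_idx)) < cfg$dropout,
                 n_lines, length(noise_idx))
  A[, noise_idx][drop] <- 0

  # technical replicates
  nrep <- cfg$replicates
  rows <- A[rep(seq_len(n_lines), each = nrep), , drop = FALSE]
  noise <- matrix(1 + cfg$noise_cv * stats::rnorm(length(rows)),
                  nrow(rows), ncol(rows))
  X <- pmax(rows * noise, 0)

  obs <- data.frame(
    line_id = rep(line_ids, each = nrep),
    class = rep(line_class, each = nrep),
    subclass = rep(unname(sub_of_line), each = nrep),
    replicate = rep(seq_len(nrep), times = n_lines),
    stringsAsFactors = FALSE)
  feats <- data.frame(feature_id = ids, rt = rt, mz = mz,
                      stringsAsFactors = FALSE)
  colnames(X) <- ids
  list(table = feature_table(X, feats, obs),
       truth = list(marker_ids = ids[roles == "marker"],
                    marker_direction = marker_dir,
                    noise_ids = ids[roles == "noise"],
                    lowmean_ids = ids[roles == "lowmean"],
                    subclass_marker_ids = sub_marker_ids))
}

#' Expected presence-filter survival of dropout features
#'
#' For a feature absent in each line independently with probability
#' `dropout`, the per-class count of lines where it is present is
#' binomial; the feature survives the presence rule iff in at least one
#' class the presence fraction reaches `frac`. Computed by exact binomial
#' tail sums.
#'
#' @param cfg a [simulation_config()].
#' @param frac presence threshold (default 0.8).
#' @return list: `p_survive` (per-feature survival probability),
#'   `expected_survivors` (`p_survive * n_noise`),
#'   `expected_removed`, `per_class` (named survival probabilities).
#' @export
expected_filter_survivors <- function(cfg, frac = 0.8) {
  stopifnot(inherits(cfg, "simulation_config"))
  sizes <- vapply(cfg$classes, length, 1L)
  p_present <- 1 - cfg$dropout
  per_class <- vapply(sizes, function(n) {
    thr <- ceiling(frac * n - 1e-9)
    stats::pbinom(thr - 1, n, p_present, lower.tail = FALSE)
  }, 0)
  p_survive <- 1 - prod(1 - per_class)
  list(p_survive = p_survive,
       expected_survivors = p_survive * cfg$n_noise,
       expected_removed = (1 - p_survive) * cfg$n_noise,
       per_class = per_class)
}
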