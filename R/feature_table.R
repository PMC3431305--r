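#' Construct a feature table
#'
#' A `feature_table` couples a nonnegative intensity matrix (observations x
#' features) with feature metadata (retention time, m/z) and observation
#' metadata (line id, class, optional subclass, replicate). Missing values
#' are not permitted: absence of a peak is encoded as intensity 0, the
#' convention of peak-alignment software exports.
#'
#' @param intensities numeric matrix, `n_obs x n_features`, all values `>= 0`.
#' @param features data.frame with columns `feature_id`, `rt` (minutes) and
#'   `mz` (daltons), one row per matrix column. If `NULL`, metadata are
#'   parsed from the matrix column names, expected in `"<rt>_<mz>"` form.
#' @param observations data.frame with columns `line_id`, `class`,
#'   `subclass` (may be `NA`) and `replicate`, one row per matrix row.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, features = NULL, observations) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(features)) {
    if (is.null(colnames(intensities)))
      stop("`features` is NULL and the intensity matrix has no column names")
    features <- parse_feature_ids(colnames(intensities))
  }
  features <- as.data.frame(features)
  observations <- as.data.frame(observations)
  if (!"subclass" %in% names(observations)) observations$subclass <- NA_character_
  needed <- c("line_id", "class", "subclass", "replicate")
  missing_cols <- setdiff(needed, names(observations))
  if (length(missing_cols))
    stop("observation metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  observations <- observations[needed]
  observations$line_id <- as.character(observations$line_id)
  observations$class <- as.character(observations$class)
  observations$subclass <- as.character(observations$subclass)
  observations$replicate <- as.integer(observations$replicate)

  if (nrow(features) != ncol(intensities))
    stop("feature metadata rows (", nrow(features),
         ") do not match intensity columns (", ncol(intensities), ")")
  if (nrow(observations) != nrow(intensities))
    stop("observation metadata rows (", nrow(observations),
         ") do not match intensity rows (", nrow(intensities), ")")
  dup <- features$feature_id[duplicated(features$feature_id)]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  key <- paste(observations$line_id, observations$replicate)
  if (anyDuplicated(key))
    stop("duplicate (line_id, replicate) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (anyNA(intensities))
    stop("intensity matrix contains missing values; encode absent peaks as 0")
  if (any(intensities < 0)) stop("intensity matrix contains negative values")
  if (any(features$rt < 0)) stop("retention times must be >= 0")
  if (any(features$mz <= 0)) stop("m/z values must be > 0")
  cls_per_line <- tapply(observations$class, observations$line_id,
                         function(x) length(unique(x)))
  if (any(cls_per_line > 1))
    stop("inconsistent class label within line(s): ",
         paste(names(cls_per_line)[cls_per_line > 1], collapse = ", "))
  colnames(intensities) <- features$feature_id
  structure(list(intensities = intensities, features = features,
                 observations = observations),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d observations x %d features\n",
              nrow(x$intensities), ncol(x$intensities)))
  cat(sprintf("  lines: %d, classes: %s\n",
              length(unique(x$observations$line_id)),
              paste(sprintf("%s (%d)", names(table(x$observations$class)),
                            table(x$observations$class)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Format and parse "<rt>_<mz>" feature identifiers
#'
#' Identifiers follow the convention of peak-table exports: retention time
#' printed at 2 decimals and m/z at up to 4 decimals, joined by an
#' underscore (e.g. `"0.49_104.1077"`). Parsing is tolerant of
#' trailing-zero variants such as `"2.25_365.316"`.
#'
#' @param rt retention times (minutes).
#' @param mz mass-to-charge ratios (daltons).
#' @return `format_feature_id`: character vector of identifiers.
#' @export
format_feature_id <- function(rt, mz) {
  sprintf("%.2f_%s", rt, sub("0+$", "", sprintf("%.4f", mz)))
}

#' @rdname format_feature_id
#' @param ids character vector of `"<rt>_<mz>"` identifiers.
#' @return `parse_feature_ids`: data.frame with `feature_id`, `rt`, `mz`.
#' @export
parse_feature_ids <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  rt <- suppressWarnings(vapply(parts, function(p) as.numeric(p[1]), 0))
  mz <- suppressWarnings(vapply(parts, function(p) as.numeric(p[length(p)]), 0))
  bad <- bad | is.na(rt) | is.na(mz)
  if (any(bad))
    stop("feature id(s) not in \"<rt>_<mz>\" form: ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  data.frame(feature_id = ids, rt = rt, mz = mz, stringsAsFactors = FALSE)
}

#' Read and write feature-table CSV files
#'
#' The on-disk dialect is a UTF-8 CSV with a header: metadata columns first
#' (by default `line_id`, `class`, `subclass`, `replicate`), then one
#' numeric column per feature, named `"<rt>_<mz>"`. `write_feature_table`
#' emits the same dialect, so read/write round-trips.
#'
#' @param path file path.
#' @param schema named list mapping the canonical metadata names
#'   (`line_id`, `class`, `subclass`, `replicate`) to the column names used
#'   in the file.
#' @return `read_feature_table`: a [feature_table()].
#' @export
read_feature_table <- function(path,
                               schema = list(line_id = "line_id", class = "class",
                                             subclass = "subclass", replicate = "replicate")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- names(raw)
  if (anyDuplicated(hdr))
    stop("duplicate column(s) in ", path, ": ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  meta_cols <- unlist(schema)
  required <- meta_cols[c("line_id", "class", "replicate")]
  missing_cols <- setdiff(required, hdr)
  if (length(missing_cols))
    stop("missing metadata column(s): ", paste(missing_cols, collapse = ", "))
  feat_cols <- setdiff(hdr, meta_cols)
  for (cc in feat_cols) {
    if (!is.numeric(raw[[cc]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(raw[[cc]]))))[1]
      stop("non-numeric intensity in column \"", cc, "\", row ", bad_row)
    }
  }
  obs <- data.frame(
    line_id = raw[[meta_cols[["line_id"]]]],
    class = raw[[meta_cols[["class"]]]],
    subclass = if (meta_cols[["subclass"]] %in% hdr)
      raw[[meta_cols[["subclass"]]]] else NA_character_,
    replicate = raw[[meta_cols[["replicate"]]]],
    stringsAsFactors = FALSE)
  feature_table(as.matrix(raw[feat_cols]), parse_feature_ids(feat_cols), obs)
}

#' @rdname read_feature_table
#' @param ft a [feature_table()].
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  out <- cbind(ft$observations, as.data.frame(ft$intensities, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Average technical replicates within each line
#'
#' Collapses the table to one row per biological line: each intensity is the
#' arithmetic mean over that line's technical replicates. Class and subclass
#' metadata are carried through; the `replicate` column becomes 1. Line
#' order follows first appearance in the input.
#'
#' @param ft a [feature_table()].
#' @return a [feature_table()] with one row per line.
#' @export
average_replicates <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  obs <- ft$observations
  lines <- unique(obs$line_id)
  idx <- match(obs$line_id, lines)
  sums <- rowsum(ft$intensities, idx, reorder = TRUE)
  counts <- tabulate(idx, nbins = length(lines))
  avg <- sums / counts
  first <- match(lines, obs$line_id)
  meta <- data.frame(line_id = lines, class = obs$class[first],
                     subclass = obs$subclass[first], replicate = 1L,
                     stringsAsFactors = FALSE)
  feature_table(avg, ft$features, meta)
}

filter_report <- function(stage_name, n_before, n_retained) {
  n_removed <- n_before - n_retained
  structure(list(stage_name = stage_name, n_before = n_before,
                 n_removed = n_removed, n_retained = n_retained,
                 removed_fraction = if (n_before > 0) n_removed / n_before else 0),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(format_filter_report(x), sep = "\n")
  invisible(x)
}

#' Serialize filter reports as a tab-separated log
#'
#' @param ... one or more `filter_report` objects (or a list of them).
#' @return character vector, one header line plus one line per stage.
#' @export
format_filter_report <- function(...) {
  reports <- list(...)
  if (length(reports) == 1 && !inherits(reports[[1]], "filter_report"))
    reports <- reports[[1]]
  rows <- vapply(reports, function(r)
    sprintf("%s\t%d\t%d\t%d\t%.1f%%", r$stage_name, r$n_before, r$n_removed,
            r$n_retained, 100 * r$removed_fraction), "")
  c("stage\tn_before\tn_removed\tn_retained\tremoved", rows)
}

#' High-quality-ion filter: class-wise presence
#'
#' Retains a feature iff, in at least one class, the fraction of that
#' class's rows with intensity strictly greater than 0 is at least `frac`
#' (inclusive). Intended to run on the replicate-averaged table, so
#' "present in a row" means the line showed the peak in at least one
#' technical replicate.
#'
#' @param ft a [feature_table()] with class labels.
#' @param frac minimum presence fraction within some class (default 0.8).
#' @return list with elements `table` (filtered [feature_table()]) and
#'   `report` (a `filter_report`).
#' @export
filter_presence <- function(ft, frac = 0.8) {
  stopifnot(inherits(ft, "feature_table"), frac > 0, frac <= 1)
  cls <- ft$observations$class
  sizes <- table(cls)
  if (any(sizes == 0)) stop("class with zero rows")
  present <- ft$intensities > 0
  keep <- rep(FALSE, ncol(ft$intensities))
  for (cl in names(sizes)) {
    fr <- colMeans(present[cls == cl, , drop = FALSE])
    keep <- keep | (fr >= frac)
  }
  rep_ <- filter_report(sprintf(">=%g%% present in a class", 100 * frac),
                        ncol(ft$intensities), sum(keep))
  list(table = subset_features(ft, keep), report = rep_)
}

#' High-quality-ion filter: minimum mean intensity
#'
#' Retains a feature iff its mean intensity across all rows (all lines,
#' pooled regardless of class) is at least `min_mean` (inclusive). Applied
#' after the presence filter on the replicate-averaged table.
#'
#' @param ft a [feature_table()].
#' @param min_mean minimum pooled mean intensity (default 1.0).
#' @return list with elements `table` and `report`, as [filter_presence()].
#' @export
filter_mean_intensity <- function(ft, min_mean = 1.0) {
  stopifnot(inherits(ft, "feature_table"))
  keep <- colMeans(ft$intensities) >= min_mean
  rep_ <- filter_report(sprintf("mean intensity >= %g", min_mean),
                        ncol(ft$intensities), sum(keep))
  list(table = subset_features(ft, keep), report = rep_)
}

subset_features <- function(ft, keep) {
  feature_table(ft$intensities[, keep, drop = FALSE],
                ft$features[keep, , drop = FALSE], ft$observations)
}

#' Pareto scaling
#'
#' Mean-centers each feature column and divides by the square root of its
#' sample standard deviation (n-1 denominator), the usual compromise
#' between no scaling and unit-variance scaling for LC-MS peak areas:
#' intense peaks are damped without inflating near-constant noise.
#' Columns with zero standard deviation become all-zero.
#'
#' @param x a [feature_table()] or numeric matrix with at least 2 rows.
#' @return list of class `pareto_scaling`: `X` (scaled matrix), `center`
#'   (per-feature means), `sd` (per-feature sample standard deviations).
#'   The parameters allow projecting new observations via [pareto_apply()].
#' @export
pareto_scale <- function(x) {
  X <- if (inherits(x, "feature_table")) x$intensities else as.matrix(x)
  if (nrow(X) < 2) stop("Pareto scaling needs at least 2 rows")
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  Xs <- sweep(X, 2, ctr)
  div <- sqrt(sds)
  div[sds == 0] <- 1
  Xs <- sweep(Xs, 2, div, "/")
  Xs[, sds == 0] <- 0
  structure(list(X = Xs, center = ctr, sd = sds), class = "pareto_scaling")
}

#' @rdname pareto_scale
#' @param scaling a `pareto_scaling` object from [pareto_scale()].
#' @param new_x matrix of raw intensities with the same feature columns as
#'   the training table.
#' @export
pareto_apply <- function(scaling, new_x) {
  stopifnot(inherits(scaling, "pareto_scaling"))
  X <- as.matrix(new_x)
  if (ncol(X) != length(scaling$center))
    stop("feature mismatch: new data has ", ncol(X), " columns, scaling has ",
         length(scaling$center))
  Xs <- sweep(X, 2, scaling$center)
  div <- sqrt(scaling$sd)
  div[scaling$sd == 0] <- 1
  Xs <- sweep(Xs, 2, div, "/")
  Xs[, scaling$sd == 0] <- 0
  Xs
}
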