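#' Single-linkage dendrogram of score vectors
#'
#' Agglomerates observations on Euclidean distances by the single-linkage
#' (nearest-neighbour) rule, the method used to visualize class structure
#' in OPLS-DA predictive-score space. Merge heights are non-decreasing
#' (single linkage is monotone); duplicate points merge at height 0.
#'
#' @param points matrix or data.frame of score vectors (rows =
#'   observations; typically the first one or two predictive score
#'   columns), or a numeric vector.
#' @param labels leaf labels (default: rownames, else `1..n`).
#' @return object of class `score_dendrogram` wrapping the `hclust` merge
#'   tree: `merge`, `height`, `labels`, `order`, plus the `hclust` object
#'   itself.
#' @export
single_linkage <- function(points, labels = NULL) {
  P <- as.matrix(points)
  if (nrow(P) < 2) stop("need at least 2 points")
  if (is.null(labels)) labels <- rownames(P)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(P)))
  hc <- stats::hclust(stats::dist(P), method = "single")
  hc$labels <- labels
  structure(list(merge = hc$merge, height = hc$height, labels = labels,
                 order = hc$order, hclust = hc, points = P),
            class = "score_dendrogram")
}

#' @export
print.score_dendrogram <- function(x, ...) {
  cat(sprintf("score_dendrogram: %d leaves, root height %.4g\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' Compactness and distinctness of dendrogram clusters
#'
#' Characterizes each internal node (cluster) of a single-linkage
#' dendrogram: *compactness* is the node's merge height — its Euclidean
#' distance from 0 on the dendrogram axis; smaller means the members are
#' more similar. *Distinctness* is the height gap from the node to its
#' parent node; larger means the cluster stays separate longer before
#' merging. The root has no parent and gets distinctness 0 by convention.
#'
#' @param d a `score_dendrogram`.
#' @param node internal node index (1-based merge index) or `NULL` for all
#'   nodes.
#' @return data.frame: `cluster` (merge index), `n_members`,
#'   `compactness`, `distinctness`, `members` (comma-joined leaf labels).
#' @export
cluster_metrics <- function(d, node = NULL) {
  stopifnot(inherits(d, "score_dendrogram"))
  n_nodes <- length(d$height)
  nodes <- if (is.null(node)) seq_len(n_nodes) else as.integer(node)
  if (any(nodes < 1 | nodes > n_nodes))
    stop("node index out of range 1..", n_nodes)
  parent <- integer(n_nodes)  # 0 = root
  for (i in seq_len(n_nodes)) {
    hit <- which(d$merge == i)
    parent[i] <- if (length(hit)) ((hit[1] - 1L) %% n_nodes) + 1L else 0L
  }
  members <- cluster_members(d)
  out <- data.frame(
    cluster = nodes,
    n_members = vapply(members[nodes], length, 1L),
    compactness = d$height[nodes],
    distinctness = ifelse(parent[nodes] == 0L, 0,
                          d$height[pmax(parent[nodes], 1L)] - d$height[nodes]),
    members = vapply(members[nodes], function(m)
      paste(d$labels[m], collapse = ","), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# leaf index sets per internal node
cluster_members <- function(d) {
  n_nodes <- length(d$height)
  members <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    kids <- d$merge[i, ]
    mem <- integer(0)
    for (kid in kids)
      mem <- c(mem, if (kid < 0) -kid else members[[kid]])
    members[[i]] <- sort(mem)
  }
  members
}

#' Cut a dendrogram into K groups
#'
#' Removes the K-1 highest merges, yielding K leaf groups — the grouping
#' compared against class labels when reading a dendrogram as a
#' classifier.
#'
#' @param d a `score_dendrogram`.
#' @param K number of groups, `1 <= K <= n_leaves`.
#' @return integer vector of group indices, named by leaf label.
#' @export
cut_to_classes <- function(d, K) {
  stopifnot(inherits(d, "score_dendrogram"))
  n <- length(d$labels)
  if (K < 1 || K > n) stop("K must be in 1..", n)
  grp <- stats::cutree(d$hclust, k = K)
  names(grp) <- d$labels
  grp
}

#' Export a dendrogram
#'
#' `dendrogram_newick` serializes the merge tree as a Newick string with
#' branch lengths equal to height differences; `dendrogram_merges` returns
#' the flat merge list (left, right, height, size).
#'
#' @param d a `score_dendrogram`.
#' @param path optional file to write the Newick string to.
#' @return `dendrogram_newick`: the Newick string, invisibly if written to
#'   a file.
#' @export
dendrogram_newick <- function(d, path = NULL) {
  stopifnot(inherits(d, "score_dendrogram"))
  phy <- ape::as.phylo(d$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname dendrogram_newick
#' @export
dendrogram_merges <- function(d) {
  stopifnot(inherits(d, "score_dendrogram"))
  members <- cluster_members(d)
  data.frame(left = d$merge[, 1], right = d$merge[, 2], height = d$height,
             size = vapply(members, length, 1L))
}
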