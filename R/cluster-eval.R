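#' Complete-linkage agglomerative clustering
#'
#' Agglomerative hierarchical clustering where the distance between two
#' clusters is the maximum pairwise distance between their members. When two
#' candidate merges share the minimal distance, the pair with the
#' lexicographically smallest index pair (by each cluster's smallest original
#' item index) is merged, so the dendrogram is fully deterministic. The
#' result is a standard `hclust` object, usable with [stats::cutree()],
#' `plot()` and [dendrogram_newick()].
#'
#' @param dist symmetric non-negative distance matrix with zero diagonal
#'   (labels from `rownames`), or a [similarity_matrix_object()] converted
#'   via [to_distance()] beforehand.
#' @return an object of class `hclust` with non-decreasing merge heights.
#' @export
complete_linkage <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  if (ncol(d) != n || !isTRUE(all.equal(d, t(d), tolerance = 1e-10))) {
    stop("distance matrix must be square and symmetric", call. = FALSE)
  }
  if (anyNA(d) || any(d < 0)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  if (any(diag(d) != 0)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("item_", seq_len(n))

  # active clusters: hclust codes (negative = singleton, positive = merge
  # step) and each cluster's smallest original member index for tie-breaking
  code <- -seq_len(n)
  minmem <- seq_len(n)
  D <- d
  diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  active <- rep(TRUE, n)

  for (s in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    mval <- min(sub)
    hits <- which(sub == mval, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # order candidate pairs by (smallest member of i, smallest member of j)
    pi <- idx[hits[, 1]]; pj <- idx[hits[, 2]]
    a <- pmin(minmem[pi], minmem[pj]); b <- pmax(minmem[pi], minmem[pj])
    best <- order(a, b)[1]
    i <- pi[best]; j <- pj[best]
    if (minmem[j] < minmem[i]) { tmp <- i; i <- j; j <- tmp }

    merge[s, ] <- sort(c(code[i], code[j]))
    height[s] <- mval
    # complete linkage: new distance is the max to either merged cluster
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      newd <- pmax(D[i, others], D[j, others])
      D[i, others] <- newd
      D[others, i] <- newd
    }
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
    code[i] <- s
    minmem[i] <- min(minmem[i], minmem[j])
  }

  hc <- list(merge = merge, height = height,
             order = tree_leaf_order(merge),
             labels = labels, method = "complete",
             call = match.call(), dist.method = "precomputed")
  class(hc) <- "hclust"
  hc
}

# internal: left-to-right leaf order of a merge tree (for plotting)
tree_leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Cut a dendrogram into k clusters
#'
#' @param dendrogram an `hclust` object (e.g. from [complete_linkage()]).
#' @param k number of clusters, `1 <= k <= n`.
#' @return an object of class `ClusterLabeling`: list with `labels`
#'   (integer assignments in `1..k`, named by item) and `k`.
#' @export
cut_tree <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$labels)
  if (length(k) != 1 || is.na(k) || k < 1 || k > n || k != round(k)) {
    stop(sprintf("k must be an integer in [1, %d]", n), call. = FALSE)
  }
  lab <- stats::cutree(dendrogram, k = k)
  structure(list(labels = lab, k = as.integer(k)), class = "ClusterLabeling")
}

#' @export
print.ClusterLabeling <- function(x, ...) {
  cat(sprintf("ClusterLabeling: %d items in %d clusters (sizes: %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items: 1
#' for identical partitions (up to label permutation), expectation 0 for
#' independent random assignments under the permutation model.
#'
#' @param a,b [cut_tree()] results, or plain label vectors of equal length.
#' @return ARI value (at most 1; can be slightly negative).
#' @export
adjusted_rand_index <- function(a, b) {
  la <- if (inherits(a, "ClusterLabeling")) a$labels else a
  lb <- if (inherits(b, "ClusterLabeling")) b$labels else b
  if (length(la) != length(lb)) {
    stop("partitions must label the same number of items", call. = FALSE)
  }
  r <- mclust::adjustedRandIndex(la, lb)
  # degenerate case (max index == expected index): both partitions are
  # trivial in the same way, so agreement is perfect
  if (is.nan(r)) r <- 1
  r
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from the merge heights, giving a diffable
#' text form of the tree.
#'
#' @param dendrogram an `hclust` object.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(dendrogram, path = NULL) {
  stopifnot(inherits(dendrogram, "hclust"))
  phy <- ape::as.phylo(dendrogram)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Convert a sequence-identity matrix to distances
#'
#' Ground-truth target relationships are given as a square identity matrix,
#' in percent (0-100) or as fractions (0-1); the distance is
#' `(100 - identity)/100` or `1 - identity` respectively. The scale is
#' auto-detected from the value range unless forced.
#'
#' @param identity labeled square numeric matrix.
#' @param percent `TRUE`/`FALSE` to force a scale, `NA` (default) to detect:
#'   any value above 1 means percent.
#' @return distance matrix in \[0, 1\] with a zero diagonal.
#' @export
identity_to_distance <- function(identity, percent = NA) {
  m <- as.matrix(identity)
  if (is.na(percent)) percent <- any(m > 1)
  d <- if (percent) (100 - m) / 100 else 1 - m
  if (any(d < 0)) stop("identity values exceed their scale", call. = FALSE)
  diag(d) <- 0
  d
}

#' Evaluate dataset representations against a ground-truth clustering
#'
#' Clusters each representation's distance matrix and the ground-truth
#' distance matrix with complete linkage at level `k`, and reports the
#' Adjusted Rand Index of each representation's partition against the
#' ground-truth partition. All matrices must share the same labels (row
#' order may differ; rows are aligned by name).
#'
#' @param distances named list of labeled distance matrices, one per
#'   representation.
#' @param ground_truth_dist labeled ground-truth distance matrix (e.g. from
#'   [identity_to_distance()]).
#' @param k number of clusters at which partitions are compared; default 10.
#' @return data.frame with columns `representation` and `ari`, sorted by
#'   decreasing ARI.
#' @export
evaluate_representations <- function(distances, ground_truth_dist, k = 10) {
  if (is.null(names(distances)) || anyDuplicated(names(distances))) {
    stop("distances must be a uniquely named list", call. = FALSE)
  }
  gt <- as.matrix(ground_truth_dist)
  labs <- rownames(gt)
  if (is.null(labs)) stop("ground truth must be labeled", call. = FALSE)
  truth <- cut_tree(complete_linkage(gt), k)
  ari <- vapply(names(distances), function(nm) {
    m <- as.matrix(distances[[nm]])
    if (is.null(rownames(m)) || !setequal(rownames(m), labs)) {
      stop(sprintf("representation '%s' does not share the ground-truth labels",
                   nm), call. = FALSE)
    }
    m <- m[labs, labs]
    part <- cut_tree(complete_linkage(m), k)
    adjusted_rand_index(part, truth)
  }, numeric(1))
  out <- data.frame(representation = names(distances), ari = unname(ari))
  out[order(-out$ari), , drop = FALSE]
}
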