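# Agglomerative clustering of side-chain conformations in torsional space.

#' Pairwise torsional distances of a conformation set
#'
#' Computes all pairwise [torsion_distance()] values for a set of
#' torsion vectors and returns them as a condensed `"dist"` object
#' (m(m-1)/2 entries, lower-triangle column order).
#'
#' @param torsions Numeric matrix (m conformations x n chi angles), or a
#'   list of equal-length numeric vectors.
#' @return A `"dist"` object of periodic torsional distances (degrees).
#' @export
pairwise_torsion_distances <- function(torsions) {
  x <- .as_torsion_matrix(torsions)
  m <- nrow(x)
  if (m < 1L) stop("at least one conformation is required")
  d2 <- matrix(0, m, m)
  for (j in seq_len(ncol(x))) {
    delta <- abs(outer(x[, j], x[, j], `-`)) %% 360
    delta <- pmin(delta, 360 - delta)
    d2 <- d2 + delta^2
  }
  stats::as.dist(sqrt(d2))
}

.as_torsion_matrix <- function(torsions) {
  if (is.list(torsions) && !is.data.frame(torsions)) {
    n <- unique(lengths(torsions))
    if (length(n) != 1L)
      stop("torsion vectors have mixed dimensions: ",
           paste(sort(unique(lengths(torsions))), collapse = ", "))
    torsions <- do.call(rbind, torsions)
  }
  x <- as.matrix(torsions)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("torsion angles must be finite")
  x
}

#' Average-linkage clustering of torsional distances
#'
#' Unweighted average-linkage (UPGMA) agglomerative clustering of a
#' condensed periodic torsional distance table, cut into flat clusters
#' at a height cutoff.  Two conformations share a flat cluster iff they
#' are joined by merges at height strictly below the cutoff, so pairs
#' merging exactly at the cutoff are split.
#'
#' @param distances A `"dist"` object, e.g. from
#'   [pairwise_torsion_distances()].
#' @param cutoff Flat-cluster cut height in degrees (default 40).
#' @return An object of class `"torsion_clustering"`: a list with
#'   `labels` (integer cluster ids 1..k, in order of first appearance),
#'   `k`, `cutoff`, `merges` (data frame `a`, `b`, `height`, `size`
#'   using the `stats::hclust` merge encoding: negative entries are
#'   leaves) and the underlying `hclust` object.
#' @export
average_linkage_cluster <- function(distances, cutoff = 40) {
  if (!inherits(distances, "dist")) stop("`distances` must be a dist object")
  m <- attr(distances, "Size")
  if (is.null(m) || m < 1L) stop("empty distance table")
  if (m == 1L) {
    merges <- data.frame(a = integer(), b = integer(),
                         height = numeric(), size = integer())
    return(structure(list(labels = 1L, k = 1L, cutoff = cutoff,
                          merges = merges, hclust = NULL),
                     class = "torsion_clustering"))
  }
  hc <- stats::hclust(distances, method = "average")
  sizes <- integer(m - 1L)
  for (i in seq_len(m - 1L)) {
    sa <- ifelse(hc$merge[i, 1L] < 0, 1L, sizes[hc$merge[i, 1L]])
    sb <- ifelse(hc$merge[i, 2L] < 0, 1L, sizes[hc$merge[i, 2L]])
    sizes[i] <- sa + sb
  }
  labels <- cut_dendrogram_strict(hc$merge, hc$height, m, cutoff)
  structure(list(labels = labels, k = max(labels), cutoff = cutoff,
                 merges = data.frame(a = hc$merge[, 1L], b = hc$merge[, 2L],
                                     height = hc$height, size = sizes),
                 hclust = hc),
            class = "torsion_clustering")
}

# Flat clusters from a merge table applying merges with height < cutoff.
cut_dendrogram_strict <- function(merge, height, m, cutoff) {
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  members <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    a <- merge[i, 1L]; b <- merge[i, 2L]
    la <- if (a < 0) -a else members[[a]][1L]
    lb <- if (b < 0) -b else members[[b]][1L]
    members[[i]] <- c(la)  # representative leaf of this internal node
    if (height[i] < cutoff) {
      ra <- find(la); rb <- find(lb)
      parent[rb] <- ra
    } else {
      # higher merges cannot rejoin below the cutoff: heights are
      # non-decreasing under average linkage
    }
  }
  roots <- vapply(seq_len(m), find, integer(1L))
  as.integer(factor(roots, levels = unique(roots)))
}

#' @export
print.torsion_clustering <- function(x, ...) {
  cat("Torsional-space average-linkage clustering\n")
  cat("  conformations:", length(x$labels), "\n")
  cat("  cutoff:", x$cutoff, "deg ->", x$k, "flat clusters\n")
  invisible(x)
}

#' Export a dendrogram merge table
#'
#' Writes the merge table (columns `a`, `b`, `height`, `size`; negative
#' ids denote leaves) as tab-separated text for external plotting.
#'
#' @param clustering A `"torsion_clustering"` object.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_dendrogram <- function(clustering, path) {
  stopifnot(inherits(clustering, "torsion_clustering"))
  utils::write.table(clustering$merges, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
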