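# Hierarchical clustering of per-subject archetypes on their pairwise
# open-ended DTW dissimilarity (average linkage), with a flat cut for
# cluster membership and Newick export of the dendrogram.

#' Cluster archetypal nights
#'
#' Computes pairwise open-ended DTW dissimilarity between archetypes,
#' builds an average-linkage dendrogram, and cuts it into `k` flat
#' clusters.
#'
#' @param archetypes List of `sw_archetype` objects (from [oe_dba()]).
#' @param k Number of flat clusters (default 2). Set `h` instead to cut at
#'   a dissimilarity height.
#' @param h Optional cut height (overrides `k`).
#' @param metric Local distance passed to [oe_dtw()].
#' @return An object of class `sw_clustering`: `hclust`, `D` (dissimilarity
#'   matrix), `clusters` (named membership vector), `labels`.
#' @export
cluster_archetypes <- function(archetypes, k = 2, h = NULL,
                               metric = "euclidean") {
  n <- length(archetypes)
  if (n < 2) stop("need at least 2 archetypes")
  labels <- vapply(seq_len(n), function(i) {
    s <- archetypes[[i]]$subject_id
    if (length(s) == 1 && nzchar(s)) s else paste0("arch", i)
  }, "")
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- oe_dtw(archetypes[[i]]$matrix,
                                 archetypes[[j]]$matrix,
                                 metric = metric)$dissimilarity
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cl <- if (is.null(h)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
  structure(list(hclust = hc, D = D, clusters = cl, labels = labels),
            class = "sw_clustering")
}

#' @export
print.sw_clustering <- function(x, ...) {
  cat(sprintf("<sw_clustering> %d archetypes in %d cluster(s)\n",
              length(x$labels), length(unique(x$clusters))))
  for (g in sort(unique(x$clusters)))
    cat(sprintf("  cluster %d: %s\n", g,
                paste(names(x$clusters)[x$clusters == g], collapse = ", ")))
  invisible(x)
}

#' Write a clustering dendrogram to Newick
#'
#' @param clustering An `sw_clustering`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "sw_clustering"))
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Rand index between two partitions
#'
#' Fraction of object pairs on which two partitions agree (both together or
#' both apart); 1 means identical partitions.
#'
#' @param a,b Membership vectors of equal length.
#' @return The Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  mean(same_a[up] == same_b[up])
}
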