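# Agglomerative clustering of fingerprints on the 1 - Tc dissimilarity,
# dendrogram export and cluster extraction.  The agglomeration itself is
# the standard algorithm (stats::hclust); determinism and row-order
# invariance are obtained by canonicalizing the leaf order (ids sorted)
# before the distance matrix is formed, so ties always break the same
# way regardless of input order.

#' Agglomerative hierarchical clustering of a similarity matrix
#'
#' Clusters on the dissimilarity `d = 1 - Tc` with the requested linkage
#' (average by default, the common choice for fingerprint Tanimoto
#' clustering).  Leaf ids are sorted before clustering, which makes the
#' result invariant to the input row order.
#'
#' @param m A `sift_simmat` (or any symmetric similarity matrix with id
#'   dimnames and values in \[0, 1\]).
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @return A `sift_tree`: list with `hc` (the merge tree), `ids` (leaf
#'   ids in canonical order) and `linkage`.
#' @export
hierarchical_cluster <- function(m, linkage = c("average", "single",
                                                "complete")) {
  linkage <- match.arg(linkage)
  m <- unclass(m)
  if (nrow(m) < 2) stop("need at least 2 items to cluster")
  stopifnot(!is.null(rownames(m)), isTRUE(all.equal(m, t(m), tolerance = 1e-8)),
            all(m >= -1e-9 & m <= 1 + 1e-9))
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  d <- stats::as.dist(1 - m)
  hc <- stats::hclust(d, method = linkage)
  structure(list(hc = hc, ids = rownames(m), linkage = linkage),
            class = "sift_tree")
}

#' @export
print.sift_tree <- function(x, ...) {
  cat("<sift_tree> ", length(x$ids), " leaves, ", x$linkage,
      " linkage, merge heights [", sprintf("%.3f", min(x$hc$height)), ", ",
      sprintf("%.3f", max(x$hc$height)), "]\n", sep = "")
  invisible(x)
}

#' Merge table of a cluster tree
#'
#' @param t A `sift_tree`.
#' @return Data frame with columns `left`, `right` (negative = leaf
#'   index, positive = earlier merge) and `height` (1 - Tc units).
#' @export
merge_table <- function(t) {
  data.frame(left = t$hc$merge[, 1], right = t$hc$merge[, 2],
             height = t$hc$height)
}

#' Cut a cluster tree into k clusters
#'
#' Removes the k-1 highest merges; labels 1..k are assigned in canonical
#' leaf order.
#'
#' @param t A `sift_tree`.
#' @param k Number of clusters, between 1 and the leaf count.
#' @return Named integer vector mapping complex id to cluster index.
#' @export
cut_tree <- function(t, k) {
  n <- length(t$ids)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  labels <- stats::cutree(t$hc, k = k)
  stats::setNames(as.integer(labels), t$ids)
}

#' Export a cluster tree as Newick text
#'
#' Merge heights become node heights (each child branch gets half the
#' merge height above its own subtree, the usual ultrametric rendering of
#' an agglomerative tree), so a two-leaf tree merged at height 0.6
#' serializes as `(a:0.3,b:0.3);`.
#'
#' @param t A `sift_tree`.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return Newick text (or the path, invisibly).
#' @export
export_dendrogram <- function(t, file = NULL) {
  phy <- ape::as.phylo(t$hc)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(file)
}

#' Write a cluster assignment as TSV
#'
#' @param labels Named vector from [cut_tree()].
#' @param file Path.
#' @export
write_assignment <- function(labels, file) {
  write.table(data.frame(id = names(labels), cluster = as.integer(labels)),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
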