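#' Euclidean distances between datasets in PC space
#'
#' @param x a \linkS4class{PcaResult} or a coordinate matrix (datasets as
#'   rows).
#' @param nPcs number of leading components to use (default 2).
#' @return symmetric d x d distance matrix with zero diagonal.
#' @export
pcDistances <- function(x, nPcs = 2L) {
  co <- if (is(x, "PcaResult")) datasetCoords(x) else as.matrix(x)
  if (nPcs > ncol(co)) stop("nPcs exceeds available components")
  as.matrix(dist(co[, seq_len(nPcs), drop = FALSE]))
}

#' Agglomerative clustering of datasets
#'
#' Hierarchical clustering (via [stats::hclust]) of the dataset distance
#' matrix; complete linkage by default.
#'
#' @param d symmetric distance matrix (e.g. from [pcDistances()]) or a
#'   \code{dist} object.
#' @param linkage \code{"complete"} (default), \code{"single"} or
#'   \code{"average"}.
#' @param nPcs recorded with the tree for provenance.
#' @return a \linkS4class{ClusterTree}.
#' @export
hierarchicalCluster <- function(d, linkage = c("complete", "single", "average"),
                                nPcs = 2L) {
  linkage <- match.arg(linkage)
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8))
      stop("validation error: distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  hc <- hclust(d, method = linkage)
  new("ClusterTree", hclust = hc, linkage = linkage, nPcs = as.integer(nPcs))
}

setMethod("show", "ClusterTree", function(object) {
  cat(sprintf("ClusterTree: %d datasets, %s linkage (first %d PCs)\n",
              length(object@hclust$labels), object@linkage, object@nPcs))
})

#' @rdname asNewick
setMethod("asNewick", "ClusterTree", function(x, file = NULL) {
  phy <- ape::as.phylo(x@hclust)
  s <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
})

#' Write the merge table of a dendrogram
#'
#' Tab-delimited merge table in \code{hclust} convention: negative entries
#' are leaves, positive entries earlier merges, with the merge height.
#'
#' @param tree a \linkS4class{ClusterTree}.
#' @param path output path.
#' @export
writeMergeTable <- function(tree, path) {
  hc <- tree@hclust
  out <- data.frame(left = hc$merge[, 1L], right = hc$merge[, 2L],
                    height = hc$height)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Does a dendrogram cut reproduce an expected partition?
#'
#' Cuts the tree into as many clusters as there are expected groups and
#' tests whether the resulting partition equals the expected one exactly
#' (group labels are immaterial).
#'
#' @param tree a \linkS4class{ClusterTree}.
#' @param groups list of character vectors partitioning the leaf labels.
#' @return TRUE iff the cut reproduces the partition.
#' @export
groupingCorrect <- function(tree, groups) {
  stopifnot(is(tree, "ClusterTree"))
  labels <- tree@hclust$labels
  flat <- unlist(groups)
  if (anyDuplicated(flat) || !setequal(flat, labels) ||
      length(flat) != length(labels))
    stop("validation error: groups must partition the leaf set")
  ct <- cutree(tree@hclust, k = length(groups))
  got <- split(names(ct), ct)
  canon <- function(p) sort(vapply(p, function(g)
    paste(sort(g), collapse = "\r"), character(1L), USE.NAMES = FALSE))
  identical(canon(got), canon(groups))
}
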