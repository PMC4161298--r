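#' Fisher's method for combining p-values
#'
#' \eqn{T = -2 \sum_i \ln p_i}, referred to a chi-square distribution with
#' 2k degrees of freedom. With a single p-value the combined p-value equals
#' the input.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @examples
#' fisherCombine(c(0.01, 0.01))  # T ~ 18.42, df 4, p ~ 1.02e-3
#' @export
fisherCombine <- function(p) {
  .checkP(p)
  T <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(statistic = T, df = df, p_value = pchisq(T, df, lower.tail = FALSE))
}

#' Non-random distribution of one disease's genes in another
#'
#' Directed cross-disease test: all genes nominally significant in the
#' source dataset (empirical p strictly below \code{alphaSelect}) are
#' carried to the target dataset, and the null hypothesis that their target
#' p-values are uniform is tested with Fisher's method. Nearby genes in
#' linkage disequilibrium violate the independence assumption, so an
#' optional pruning step drops the latter gene of any pair within
#' \code{pruneCm} cM before combining.
#'
#' @param source,target \linkS4class{GeneScores} for the two datasets.
#' @param alphaSelect nominal selection threshold in the source (default
#'   0.01, strict inequality).
#' @param pruneCm optional minimum cM separation; requires \code{genePos}.
#' @param genePos data.frame \code{gene_id}, \code{chrom}, \code{cm} with
#'   genetic midpoints, needed only when \code{pruneCm} is given.
#' @return a \linkS4class{CrossTestResult}; when no gene is selected the
#'   result is flagged untestable and carries no p-value.
#' @export
fisherNonrandom <- function(source, target, alphaSelect = 0.01,
                            pruneCm = NULL, genePos = NULL) {
  stopifnot(is(source, "GeneScores"), is(target, "GeneScores"))
  if (alphaSelect <= 0 || alphaSelect >= 1)
    stop("alphaSelect must lie in (0,1)")
  shared <- intersect(source@table$gene_id, target@table$gene_id)
  st <- source@table[match(shared, source@table$gene_id), , drop = FALSE]
  sel <- st$gene_id[st$empirical_p < alphaSelect]
  pruned <- FALSE
  if (!is.null(pruneCm) && length(sel)) {
    if (is.null(genePos))
      stop("pruning requires gene positions (genePos)")
    pos <- genePos[match(sel, genePos$gene_id), , drop = FALSE]
    if (any(is.na(pos$cm)))
      stop("validation error: missing cM coordinate for selected gene(s)")
    sel <- pruneByDistance(
      data.frame(gene_id = sel, chrom = pos$chrom, cm = pos$cm,
                 stringsAsFactors = FALSE),
      minSep = pruneCm)$gene_id
    pruned <- TRUE
  }
  k <- length(sel)
  if (k == 0L)
    return(new("CrossTestResult", source = source@datasetId,
               target = target@datasetId, k = 0L, statistic = 0,
               df = 0L, pValue = NA_real_, pruned = pruned,
               testable = FALSE))
  tt <- target@table
  pTarget <- tt$empirical_p[match(sel, tt$gene_id)]
  fc <- fisherCombine(pTarget)
  new("CrossTestResult", source = source@datasetId,
      target = target@datasetId, k = k, statistic = fc$statistic,
      df = as.integer(fc$df), pValue = fc$p_value, pruned = pruned,
      testable = TRUE)
}

setMethod("show", "CrossTestResult", function(object) {
  if (object@testable)
    cat(sprintf(
      "CrossTest %s -> %s: k = %d genes%s, T = %.3f (df %d), p = %.3g\n",
      object@source, object@target, object@k,
      if (object@pruned) " (pruned)" else "",
      object@statistic, object@df, object@pValue))
  else
    cat(sprintf("CrossTest %s -> %s: no gene selected (untestable)\n",
                object@source, object@target))
})

#' All directed cross-disease tests
#'
#' Runs [fisherNonrandom()] for every ordered dataset pair.
#'
#' @param tables list of \linkS4class{GeneScores} (>= 2).
#' @inheritParams fisherNonrandom
#' @return data.frame with one row per ordered pair: \code{source},
#'   \code{target}, \code{k}, \code{statistic}, \code{df}, \code{p_value},
#'   \code{pruned}, \code{testable}.
#' @export
fisherMatrix <- function(tables, alphaSelect = 0.01, pruneCm = NULL,
                         genePos = NULL) {
  if (length(tables) < 2L) stop("validation error: need at least two datasets")
  ids <- vapply(tables, function(t) t@datasetId, character(1L))
  rows <- list()
  for (i in seq_along(tables)) for (j in seq_along(tables)) {
    if (i == j) next
    r <- fisherNonrandom(tables[[i]], tables[[j]], alphaSelect,
                         pruneCm, genePos)
    rows[[length(rows) + 1L]] <- data.frame(
      source = r@source, target = r@target, k = r@k,
      statistic = r@statistic, df = r@df, p_value = r@pValue,
      pruned = r@pruned, testable = r@testable, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pivot Fisher results into a matrix
#'
#' @param ft data.frame from [fisherMatrix()].
#' @param value \code{"p"} for raw p-values or \code{"neglog10p"}.
#' @return square matrix, source datasets as rows, targets as columns
#'   (diagonal and untestable entries NA).
#' @export
fisherPMatrix <- function(ft, value = c("neglog10p", "p")) {
  value <- match.arg(value)
  ids <- sort(unique(c(ft$source, ft$target)))
  M <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  v <- if (value == "p") ft$p_value else -log10(ft$p_value)
  M[cbind(match(ft$source, ids), match(ft$target, ids))] <- v
  M
}

#' Export a Fisher matrix as TSV
#'
#' -log10 p-values, source datasets as rows, targets as columns.
#'
#' @param ft data.frame from [fisherMatrix()].
#' @param path output path.
#' @export
writeFisherMatrix <- function(ft, path) {
  M <- fisherPMatrix(ft, "neglog10p")
  out <- data.frame(source = rownames(M), M, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
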