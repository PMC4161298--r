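#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx cor cor.test cutree dist hclust pchisq pt runif
#'   setNames
#' @importFrom utils read.table write.table head modifyList
NULL

#' Piecewise-linear genetic map
#'
#' Holds, per chromosome, a monotone table of physical position (bp) versus
#' cumulative genetic position (cM). Queries between map points are linearly
#' interpolated; queries outside the mapped range are clamped to the boundary
#' cM value, so extrapolation can never produce negative or runaway genetic
#' positions at chromosome ends.
#'
#' @slot maps named list, one element per chromosome, each a data.frame with
#'   columns \code{pos_bp} (increasing integer) and \code{cm} (nondecreasing
#'   numeric).
#' @seealso [readGeneticMap()], [interpolateCM()]
#' @export
setClass("GeneticMap", representation(maps = "list"))

setValidity("GeneticMap", function(object) {
  for (chrom in names(object@maps)) {
    m <- object@maps[[chrom]]
    if (!all(c("pos_bp", "cm") %in% names(m)))
      return(sprintf("map for chromosome %s lacks pos_bp/cm columns", chrom))
    if (is.unsorted(m$pos_bp, strictly = TRUE))
      return(sprintf("positions not strictly increasing on chromosome %s", chrom))
    if (is.unsorted(m$cm))
      return(sprintf("cM not nondecreasing on chromosome %s", chrom))
  }
  TRUE
})

#' SNP-to-gene assignment
#'
#' Result of [mapSnpsToGenes()]: each SNP is assigned to at most one gene
#' (the nearest gene whose window covers it) or discarded. Rows are aligned
#' with the SNP table the mapping was built from, in (chromosome, position)
#' order.
#'
#' @slot snpId character, SNP identifiers in genome order.
#' @slot geneId character, assigned gene per SNP (\code{NA} = discarded).
#' @slot mode \code{"genetic"} (window in cM) or \code{"physical"} (bp).
#' @slot window numeric window half-width used for assignment.
#' @export
setClass("SnpGeneMap", representation(
  snpId = "character", geneId = "character",
  mode = "character", window = "numeric"
))

setValidity("SnpGeneMap", function(object) {
  if (length(object@snpId) != length(object@geneId))
    return("snpId and geneId lengths differ")
  if (!object@mode %in% c("genetic", "physical"))
    return("mode must be 'genetic' or 'physical'")
  if (length(object@window) != 1L || object@window <= 0)
    return("window must be a single positive number")
  TRUE
})

#' Gene-level scores for one GWAS dataset
#'
#' Per-gene combination statistics and empirical p-values for a single
#' dataset, calibrated against random groups of consecutive SNPs. The
#' empirical p-value carries a +1/+1 pseudocount, so it is bounded below by
#' 1/(N+1) and \code{-log10} of it stays finite.
#'
#' @slot datasetId scalar character.
#' @slot table data.frame with columns \code{gene_id}, \code{n_snps},
#'   \code{raw_stat}, \code{empirical_p}.
#' @slot method one of \code{min_p}, \code{trunc_product},
#'   \code{trunc_tail_strength}.
#' @slot tau truncation point used by the truncated methods.
#' @slot nullSize number of null SNP groups per distinct SNP count.
#' @slot seed integer seed the null sampling was run under.
#' @export
setClass("GeneScores", representation(
  datasetId = "character", table = "data.frame", method = "character",
  tau = "numeric", nullSize = "integer", seed = "integer"
))

setValidity("GeneScores", function(object) {
  tab <- object@table
  need <- c("gene_id", "n_snps", "raw_stat", "empirical_p")
  if (!all(need %in% names(tab)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tab$gene_id)) return("duplicate gene_id in table")
  if (nrow(tab) && any(tab$n_snps < 1L)) return("scored genes must have n_snps >= 1")
  N <- object@nullSize
  if (nrow(tab) && (any(tab$empirical_p < 1 / (N + 1) - 1e-12) ||
                    any(tab$empirical_p > 1)))
    return("empirical_p outside [1/(N+1), 1]")
  TRUE
})

#' Dataset-by-gene score matrix
#'
#' A \linkS4class{SummarizedExperiment} holding the matrix of -log10
#' gene-level empirical p-values over the genes shared by all input datasets
#' (genes as rows, datasets as columns, per the container's convention), with
#' study-level covariates in \code{colData}. The mathematical object used
#' throughout the method is its transpose Z (datasets x genes), returned by
#' [scoreMatrix()].
#'
#' @seealso [buildScoreMatrix()], [runPCA()], [residualize()]
#' @export
setClass("ScoreMatrix", contains = "SummarizedExperiment")

setValidity("ScoreMatrix", function(object) {
  if (!"score" %in% SummarizedExperiment::assayNames(object))
    return("assay 'score' missing")
  m <- SummarizedExperiment::assay(object, "score")
  if (!all(is.finite(m))) return("score entries must be finite")
  if (any(m < 0)) return("score entries must be >= 0 (-log10 p-values)")
  cd <- names(SummarizedExperiment::colData(object))
  need <- c("array_label", "method_label", "sample_size")
  if (!all(need %in% cd))
    return(paste("colData must carry:", paste(need, collapse = ", ")))
  if (anyDuplicated(colnames(object))) return("duplicate dataset ids")
  if (anyDuplicated(rownames(object))) return("duplicate gene ids")
  TRUE
})

#' Centered SVD / PCA of a score matrix
#'
#' @slot coords d x k dataset coordinates ("scores": centered or residualized
#'   matrix times the gene loadings; equivalently U D).
#' @slot pcs d x k left singular vectors (unit norm); what the dataset
#'   positions look like before scaling by the singular values.
#' @slot loadings g x k gene loadings (right singular vectors, unit norm).
#' @slot eigenvalues squared singular values, nonincreasing.
#' @slot varianceFraction fraction of total variance per component.
#' @slot source \code{"raw"} or \code{"residualized"}.
#' @export
setClass("PcaResult", representation(
  coords = "matrix", pcs = "matrix", loadings = "matrix",
  eigenvalues = "numeric", varianceFraction = "numeric", source = "character"
))

setValidity("PcaResult", function(object) {
  k <- length(object@eigenvalues)
  if (ncol(object@coords) != k || ncol(object@loadings) != k)
    return("component count mismatch between slots")
  if (is.unsorted(rev(object@eigenvalues))) return("eigenvalues must be nonincreasing")
  if (any(object@eigenvalues < -1e-8)) return("eigenvalues must be nonnegative")
  TRUE
})

#' Per-gene confounder regression report
#'
#' Ordinary least-squares tests of each gene's cross-dataset score vector
#' against the encoded study covariates, with a Bonferroni flag per covariate
#' column across genes.
#'
#' @slot table long data.frame: \code{gene_id}, \code{covariate},
#'   \code{estimate}, \code{p_value}, \code{significant}.
#' @slot alpha family-wise significance level used for flagging.
#' @slot nGenes number of genes tested (the Bonferroni denominator).
#' @export
setClass("ConfounderReport", representation(
  table = "data.frame", alpha = "numeric", nGenes = "integer"
))

#' Hierarchical clustering of datasets in PC space
#'
#' Thin wrapper around a [stats::hclust] tree built from Euclidean distances
#' between dataset coordinates on the leading principal components, so it can
#' be cut, compared against expected partitions, and serialized to Newick.
#'
#' @slot hclust the underlying \code{hclust} object.
#' @slot linkage agglomeration method used.
#' @slot nPcs how many leading components the distances were computed over.
#' @export
setClass("ClusterTree", representation(
  hclust = "ANY", linkage = "character", nPcs = "integer"
))

setValidity("ClusterTree", function(object) {
  if (!inherits(object@hclust, "hclust")) return("hclust slot must be an hclust object")
  TRUE
})

#' Fisher's-method cross-disease test result
#'
#' Directed test: genes nominally significant in the source dataset are
#' tested for a non-uniform p-value distribution in the target dataset via
#' Fisher's combined statistic, chi-square with 2k degrees of freedom.
#'
#' @slot source,target dataset identifiers.
#' @slot k number of selected (and optionally distance-pruned) genes.
#' @slot statistic Fisher statistic, -2 sum(ln p).
#' @slot df degrees of freedom, 2k.
#' @slot pValue upper-tail chi-square p-value (NA when untestable).
#' @slot pruned whether nearby-gene pruning was applied before combining.
#' @slot testable FALSE when no gene passed selection (k = 0).
#' @export
setClass("CrossTestResult", representation(
  source = "character", target = "character", k = "integer",
  statistic = "numeric", df = "integer", pValue = "numeric",
  pruned = "logical", testable = "logical"
))

setValidity("CrossTestResult", function(object) {
  if (object@testable && object@statistic < 0) return("statistic must be >= 0")
  if (object@df %% 2L != 0L) return("degrees of freedom must be even")
  if (object@testable && (object@pValue < 0 || object@pValue > 1))
    return("pValue outside [0,1]")
  TRUE
})

#' Design of the pleiotropy p-value simulation
#'
#' Two disease classes of \code{nPerClass} diseases each and \code{nGenes}
#' genes. Three disjoint gene sets drive the structure: a background set
#' (uniform p-values in every disease), a class-wide pleiotropic set
#' (p ~ U(0, pSignal) in every class-A disease), and a cross-class quartet
#' set (p ~ U(0, pSignal) in A1, A2, B1, B2 only).
#'
#' @slot nPerClass diseases per class (default 5).
#' @slot nGenes total genes (default 10000).
#' @slot set2Size size of the class-A pleiotropic set.
#' @slot set3Size size of the cross-class quartet set.
#' @slot pSignal upper bound of the signal p-value distribution (default 0.05).
#' @export
setClass("SimulationDesign", representation(
  nPerClass = "integer", nGenes = "integer", set2Size = "integer",
  set3Size = "integer", pSignal = "numeric"
))

setValidity("SimulationDesign", function(object) {
  if (object@nPerClass < 1L) return("nPerClass must be >= 1")
  if (object@set2Size < 0L || object@set3Size < 0L) return("set sizes must be >= 0")
  if (object@set2Size + object@set3Size > object@nGenes)
    return("signal sets exceed the number of genes")
  if (object@pSignal <= 0 || object@pSignal > 1) return("pSignal must be in (0,1]")
  TRUE
})
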