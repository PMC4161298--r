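#' Dataset-by-gene matrix of -log10 gene p-values
#'
#' Returns the d x g matrix Z with one row per GWAS dataset and one column
#' per shared gene, entries \code{-log10(empirical_p)}.
#'
#' @param x a \linkS4class{ScoreMatrix}.
#' @return numeric matrix, datasets as rows.
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname scoreMatrix
#' @export
setGeneric("datasetIds", function(x) standardGeneric("datasetIds"))

#' @rdname scoreMatrix
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Study covariates aligned to datasets
#'
#' @param x a \linkS4class{ScoreMatrix}.
#' @return data.frame with \code{dataset_id}, \code{array_label},
#'   \code{method_label}, \code{sample_size}.
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' Accessors for PCA results
#'
#' \code{datasetCoords} are the projections of the (centered or residualized)
#' dataset rows onto the components, used for plotting and clustering;
#' \code{leftSingularVectors} are the same positions before scaling by the
#' singular values; \code{geneLoadings} are the right singular vectors;
#' \code{eigenvalues} the squared singular values; \code{varianceFractions}
#' each component's share of total variance.
#'
#' @param x a \linkS4class{PcaResult}.
#' @name pca-accessors
NULL

#' @rdname pca-accessors
#' @export
setGeneric("datasetCoords", function(x) standardGeneric("datasetCoords"))

#' @rdname pca-accessors
#' @export
setGeneric("geneLoadings", function(x) standardGeneric("geneLoadings"))

#' @rdname pca-accessors
#' @export
setGeneric("leftSingularVectors", function(x) standardGeneric("leftSingularVectors"))

#' @rdname pca-accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname pca-accessors
#' @export
setGeneric("varianceFractions", function(x) standardGeneric("varianceFractions"))

#' Residualize gene scores on study covariates
#'
#' Replaces each gene's cross-dataset vector with its ordinary least-squares
#' residual after regression on an intercept plus the encoded covariates
#' (one-hot genotyping array and association method, log10 sample size).
#' Every column of the result is orthogonal to every design column.
#'
#' @param x a \linkS4class{ScoreMatrix}, or a d x g numeric matrix.
#' @param ... for the matrix method, \code{covariates}: a covariate
#'   data.frame with one row per dataset.
#' @return d x g numeric matrix of residuals.
#' @export
setGeneric("residualize", function(x, ...) standardGeneric("residualize"))

#' Centered, unscaled PCA via singular value decomposition
#'
#' Columns are mean-centered (no variance scaling), the SVD is taken, and
#' components are ordered by nonincreasing squared singular value. The
#' component sign is fixed by forcing the largest-magnitude gene loading in
#' each component to be positive, so output is reproducible across
#' linear-algebra backends.
#'
#' @param x a \linkS4class{ScoreMatrix} or a d x g numeric matrix
#'   (datasets as rows).
#' @param ... \code{residualized = FALSE}: for the ScoreMatrix method,
#'   regress out study covariates before the decomposition.
#' @return a \linkS4class{PcaResult}.
#' @export
setGeneric("runPCA", function(x, ...) standardGeneric("runPCA"))

#' Newick serialization of a dataset dendrogram
#'
#' @param x a \linkS4class{ClusterTree}.
#' @param file optional path; when given the string is also written there.
#' @return Newick string (invisibly when \code{file} is given). Branch
#'   lengths follow the ultrametric convention (internal nodes at half the
#'   merge height), so tip-to-tip cophenetic distances equal the merge
#'   heights.
#' @export
setGeneric("asNewick", function(x, file = NULL) standardGeneric("asNewick"))
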