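.newScoreMatrix <- function(Z, cov) {
  cov <- as.data.frame(cov)
  if (!all(rownames(Z) %in% cov$dataset_id))
    stop("validation error: dataset(s) missing from the covariate table: ",
         paste(setdiff(rownames(Z), cov$dataset_id), collapse = ", "))
  cov <- cov[match(rownames(Z), cov$dataset_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(array_label = cov$array_label,
                             method_label = cov$method_label,
                             sample_size = cov$sample_size,
                             row.names = rownames(Z))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(score = t(Z)), colData = cd)
  new("ScoreMatrix", se)
}

#' Assemble the dataset-by-gene score matrix
#'
#' Intersects the gene sets of all input gene-score tables (only genes
#' scored in every dataset are kept, sorted by gene id), takes
#' \code{-log10(empirical_p)}, and attaches the study covariates.
#'
#' @param tables list of \linkS4class{GeneScores}, one per dataset, in the
#'   desired row order.
#' @param covariates covariate data.frame (see [readCovariates()]) covering
#'   every dataset.
#' @return a \linkS4class{ScoreMatrix}.
#' @export
buildScoreMatrix <- function(tables, covariates) {
  if (length(tables) < 2L) stop("need at least two datasets")
  ids <- vapply(tables, function(t) t@datasetId, character(1L))
  if (anyDuplicated(ids)) stop("duplicate dataset ids")
  shared <- Reduce(intersect, lapply(tables, function(t) t@table$gene_id))
  if (!length(shared))
    stop("validation error: no gene is shared by all datasets")
  shared <- sort(shared)
  Z <- do.call(rbind, lapply(tables, function(t) {
    tab <- t@table
    -log10(tab$empirical_p[match(shared, tab$gene_id)])
  }))
  dimnames(Z) <- list(ids, shared)
  .newScoreMatrix(Z, covariates)
}

#' @rdname scoreMatrix
setMethod("scoreMatrix", "ScoreMatrix", function(x)
  t(SummarizedExperiment::assay(x, "score")))

#' @rdname scoreMatrix
setMethod("datasetIds", "ScoreMatrix", function(x) colnames(x))

#' @rdname scoreMatrix
setMethod("geneIds", "ScoreMatrix", function(x) rownames(x))

#' @rdname covariates
setMethod("covariates", "ScoreMatrix", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(dataset_id = rownames(cd), array_label = cd$array_label,
             method_label = cd$method_label, sample_size = cd$sample_size,
             stringsAsFactors = FALSE)
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d datasets x %d shared genes\n",
              ncol(object), nrow(object)))
  cat("  datasets:", paste(head(colnames(object), 8L), collapse = ", "),
      if (ncol(object) > 8L) "..." else "", "\n")
})

#' Column-center a matrix
#'
#' Subtracts each column's mean, so every column of the result sums to zero.
#'
#' @param Z numeric matrix with finite entries.
#' @return centered matrix of the same shape.
#' @export
centerColumns <- function(Z) {
  if (!all(is.finite(Z))) stop("validation error: non-finite entries")
  sweep(Z, 2L, colMeans(Z), "-")
}

# Encoded design matrix: intercept + one-hot array & method (first level as
# reference) + log10 sample size. Constant categorical covariates contribute
# no column.
.designMatrix <- function(cov) {
  df <- data.frame(array_label = factor(cov$array_label),
                   method_label = factor(cov$method_label),
                   log10_n = log10(cov$sample_size))
  terms <- c(
    if (nlevels(df$array_label) > 1L) "array_label",
    if (nlevels(df$method_label) > 1L) "method_label",
    if (length(unique(df$log10_n)) > 1L) "log10_n")
  form <- if (length(terms))
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  else ~1
  X <- stats::model.matrix(form, df)
  rownames(X) <- cov$dataset_id
  X
}

.checkDesign <- function(X, d) {
  if (qr(X)$rank < ncol(X)) {
    stop("configuration error: collinear covariate design (columns: ",
         paste(colnames(X), collapse = ", "), ")")
  }
  if (ncol(X) >= d)
    stop("configuration error: more design columns than datasets - 1")
  invisible(X)
}

#' Test genes for association with study covariates
#'
#' For each gene, ordinary least squares of its length-d score vector on an
#' intercept plus the encoded covariates; two-sided t-tests per coefficient;
#' Bonferroni-corrected flags at \code{alpha} across genes, per covariate
#' column. Genes flagged here track study design (array, association
#' method, sample size) rather than disease biology.
#'
#' @param sm a \linkS4class{ScoreMatrix}.
#' @param alpha family-wise error level for the Bonferroni flag.
#' @return a \linkS4class{ConfounderReport}.
#' @export
testConfounders <- function(sm, alpha = 0.05) {
  stopifnot(is(sm, "ScoreMatrix"))
  Z <- scoreMatrix(sm)
  X <- .designMatrix(covariates(sm))
  .checkDesign(X, nrow(Z))
  qrX <- qr(X)
  beta <- qr.coef(qrX, Z)                      # p x g
  res <- qr.resid(qrX, Z)
  df <- nrow(Z) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtxInv <- chol2inv(qr.R(qrX))
  se <- sqrt(outer(diag(xtxInv), sigma2))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  keep <- setdiff(rownames(beta), "(Intercept)")
  g <- ncol(Z)
  tab <- do.call(rbind, lapply(keep, function(cv) data.frame(
    gene_id = colnames(Z), covariate = cv,
    estimate = beta[cv, ], p_value = pval[cv, ],
    significant = pval[cv, ] < alpha / g,
    stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  new("ConfounderReport", table = tab, alpha = alpha, nGenes = as.integer(g))
}

setMethod("show", "ConfounderReport", function(object) {
  nsig <- sum(object@table$significant)
  cat(sprintf(
    "ConfounderReport: %d genes x %d covariate columns; %d flagged (Bonferroni, alpha = %g)\n",
    object@nGenes, length(unique(object@table$covariate)), nsig, object@alpha))
})

#' @rdname residualize
setMethod("residualize", "ScoreMatrix", function(x, ...)
  residualize(scoreMatrix(x), covariates = covariates(x)))

#' @rdname residualize
setMethod("residualize", "matrix", function(x, covariates, ...) {
  X <- .designMatrix(covariates)
  .checkDesign(X, nrow(x))
  R <- qr.resid(qr(X), x)
  dimnames(R) <- dimnames(x)
  R
})

.pcaFromMatrix <- function(M, source) {
  if (!all(is.finite(M))) stop("validation error: non-finite entries")
  if (nrow(M) < 2L) stop("need at least two datasets (rows)")
  B <- centerColumns(M)
  sv <- svd(B)
  k <- length(sv$d)
  # sign convention: largest-|loading| entry positive per component
  for (i in seq_len(k)) {
    j <- which.max(abs(sv$v[, i]))
    if (sv$v[j, i] < 0) {
      sv$v[, i] <- -sv$v[, i]
      sv$u[, i] <- -sv$u[, i]
    }
  }
  ev <- sv$d^2
  coords <- sv$u %*% diag(sv$d, k, k)
  cn <- paste0("PC", seq_len(k))
  dimnames(coords) <- list(rownames(M), cn)
  dimnames(sv$u) <- list(rownames(M), cn)
  dimnames(sv$v) <- list(colnames(M), cn)
  tot <- sum(ev)
  new("PcaResult", coords = coords, pcs = sv$u, loadings = sv$v,
      eigenvalues = ev,
      varianceFraction = if (tot > 0) ev / tot else rep(NA_real_, k),
      source = source)
}

#' @rdname runPCA
setMethod("runPCA", "matrix", function(x, ...) .pcaFromMatrix(x, "raw"))

#' @rdname runPCA
#' @param residualized regress study covariates out of the score matrix
#'   before the decomposition.
setMethod("runPCA", "ScoreMatrix", function(x, residualized = FALSE, ...) {
  if (residualized) .pcaFromMatrix(residualize(x), "residualized")
  else .pcaFromMatrix(scoreMatrix(x), "raw")
})

#' @rdname pca-accessors
setMethod("datasetCoords", "PcaResult", function(x) x@coords)

#' @rdname pca-accessors
setMethod("geneLoadings", "PcaResult", function(x) x@loadings)

#' @rdname pca-accessors
setMethod("leftSingularVectors", "PcaResult", function(x) x@pcs)

#' @rdname pca-accessors
setMethod("eigenvalues", "PcaResult", function(x) x@eigenvalues)

#' @rdname pca-accessors
setMethod("varianceFractions", "PcaResult", function(x) x@varianceFraction)

setMethod("show", "PcaResult", function(object) {
  k <- min(4L, length(object@eigenvalues))
  cat(sprintf("PcaResult (%s): %d datasets, %d genes, %d components\n",
              object@source, nrow(object@coords), nrow(object@loadings),
              length(object@eigenvalues)))
  cat("  variance fractions:",
      paste(sprintf("%s %.1f%%", paste0("PC", seq_len(k)),
                    100 * object@varianceFraction[seq_len(k)]),
            collapse = ", "), "...\n")
})

#' Genes with the largest absolute loadings
#'
#' Ranks genes by the mean of their absolute loadings over the given
#' components and returns the top k (ties broken by gene id).
#'
#' @param pca a \linkS4class{PcaResult}.
#' @param pcs component indices to average over (default first two).
#' @param k number of genes to return (default 50).
#' @return data.frame \code{gene_id}, \code{mean_abs_loading}, ranked.
#' @export
topLoadingGenes <- function(pca, pcs = 1:2, k = 50L) {
  stopifnot(is(pca, "PcaResult"))
  if (any(pcs > ncol(pca@loadings)) || any(pcs < 1L))
    stop("invalid component indices")
  if (k < 1L) stop("k must be >= 1")
  score <- rowMeans(abs(pca@loadings[, pcs, drop = FALSE]))
  ids <- rownames(pca@loadings)
  ord <- order(-score, ids)
  sel <- ord[seq_len(min(k, length(ord)))]
  data.frame(gene_id = ids[sel], mean_abs_loading = score[sel],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Drop the latter of nearby gene pairs
#'
#' Scans genes in genomic order (chromosome, then cM) and, whenever a gene
#' lies within \code{minSep} cM of the most recent retained gene on the same
#' chromosome, drops the one with the larger coordinate (the "latter").
#' Used to thin linked genes before enrichment or Fisher combination, where
#' nearby genes violate independence.
#'
#' @param genes data.frame with \code{gene_id}, \code{chrom}, \code{cm}
#'   (genetic midpoint); any other columns pass through.
#' @param minSep minimum separation in cM (default 0.1).
#' @return the retained rows of \code{genes}, in the original row order.
#' @export
pruneByDistance <- function(genes, minSep = 0.1) {
  need <- c("gene_id", "chrom", "cm")
  if (!all(need %in% names(genes)))
    stop("genes must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(genes$cm)))
    stop("validation error: missing cM coordinate")
  ord <- order(genes$chrom, genes$cm)
  keep <- logical(nrow(genes))
  lastChrom <- NA_character_; lastCm <- -Inf
  for (i in ord) {
    if (!identical(genes$chrom[i], lastChrom) ||
        genes$cm[i] - lastCm > minSep) {
      keep[i] <- TRUE
      lastChrom <- genes$chrom[i]
      lastCm <- genes$cm[i]
    }
  }
  genes[keep, , drop = FALSE]
}

#' Correlation of gene loadings between two analyses
#'
#' Replication check: selects the k genes with the largest average absolute
#' loading (mean over the requested components, averaged across the two
#' analyses, restricted to their shared gene universe), aligns component
#' signs (a principal component is defined only up to sign), and returns the
#' Pearson correlation between the two mean loading vectors with its
#' two-sided t-distribution p-value.
#'
#' @param pcaA,pcaB \linkS4class{PcaResult} objects over overlapping gene
#'   universes.
#' @param pcs components to average over (default first two).
#' @param k genes to select (default 50; at least 3 required).
#' @return list with \code{r}, \code{p_value}, \code{k}, \code{genes}.
#' @export
correlateLoadings <- function(pcaA, pcaB, pcs = 1:2, k = 50L) {
  stopifnot(is(pcaA, "PcaResult"), is(pcaB, "PcaResult"))
  shared <- intersect(rownames(pcaA@loadings), rownames(pcaB@loadings))
  if (length(shared) < 3L)
    stop("validation error: fewer than 3 shared genes")
  LA <- pcaA@loadings[shared, pcs, drop = FALSE]
  LB <- pcaB@loadings[shared, pcs, drop = FALSE]
  avg <- (rowMeans(abs(LA)) + rowMeans(abs(LB))) / 2
  k <- min(k, length(shared))
  if (k < 3L) stop("k must be >= 3")
  sel <- names(sort(avg, decreasing = TRUE))[seq_len(k)]
  LA <- LA[sel, , drop = FALSE]; LB <- LB[sel, , drop = FALSE]
  for (j in seq_along(pcs)) {
    if (isTRUE(cor(LA[, j], LB[, j]) < 0)) LB[, j] <- -LB[, j]
  }
  ct <- cor.test(rowMeans(LA), rowMeans(LB))
  list(r = unname(ct$estimate), p_value = ct$p.value, k = k, genes = sel)
}

#' Exclude genes in a genomic region
#'
#' Generic region filter on gene intervals; the default drops the major
#' histocompatibility complex and flanking sequence on chromosome 6, whose
#' dense association signals can dominate cross-disease structure.
#'
#' @param genes gene data.frame (1-based closed intervals).
#' @param chrom,start_bp,end_bp region to exclude (defaults
#'   chr6:25,000,000-35,000,000).
#' @return \code{genes} without the genes overlapping the region.
#' @export
excludeRegion <- function(genes, chrom = "6",
                          start_bp = 25000000L, end_bp = 35000000L) {
  hit <- genes$chrom == chrom &
    genes$start_bp <= end_bp & genes$end_bp >= start_bp
  genes[!hit, , drop = FALSE]
}
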