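#' Gene-level p-value combination statistics
#'
#' Three ways to collapse the association p-values of the SNPs mapped to a
#' gene into one statistic:
#' \describe{
#'   \item{\code{minPStat}}{the minimum p-value; smaller is more significant.}
#'   \item{\code{truncProductStat}}{product of all p-values at or below the
#'     truncation point \code{tau}; an empty selection gives 1; smaller is
#'     more significant.}
#'   \item{\code{truncTailStrengthStat}}{with k the total SNP count and
#'     p_(j) the ascending order statistics, (1/k) * sum over j with
#'     p_(j) <= tau of (1 - p_(j) * (k+1)/j); larger is more significant
#'     (exact uniform quantiles give 0).}
#' }
#'
#' @param p numeric vector of p-values in (0, 1], nonempty.
#' @param tau truncation point in (0, 1].
#' @return scalar statistic.
#' @examples
#' minPStat(c(0.5, 0.01, 0.9))                  # 0.01
#' truncProductStat(c(0.01, 0.04, 0.5), 0.05)   # 4e-4
#' truncTailStrengthStat(c(0.1, 0.2, 0.3), 1)   # 0.6
#' @name gene-statistics
NULL

.checkP <- function(p) {
  if (!length(p)) stop("validation error: empty p-value set")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0,1]")
}

.checkTau <- function(tau) {
  if (length(tau) != 1L || tau <= 0 || tau > 1)
    stop("configuration error: tau must lie in (0,1]")
}

#' @rdname gene-statistics
#' @export
minPStat <- function(p) {
  .checkP(p)
  min(p)
}

#' @rdname gene-statistics
#' @export
truncProductStat <- function(p, tau = 0.05) {
  .checkP(p); .checkTau(tau)
  sel <- p[p <= tau]
  if (!length(sel)) 1.0 else prod(sel)
}

#' @rdname gene-statistics
#' @export
truncTailStrengthStat <- function(p, tau = 0.05) {
  .checkP(p); .checkTau(tau)
  k <- length(p)
  ps <- sort(p)
  j <- seq_len(k)
  keep <- ps <= tau
  sum(1 - ps[keep] * (k + 1) / j[keep]) / k
}

# unchecked dispatcher used in the null-sampling hot loop
.statFun <- function(method, tau) {
  switch(method,
    min_p = function(p) min(p),
    trunc_product = function(p) {
      sel <- p[p <= tau]
      if (!length(sel)) 1.0 else prod(sel)
    },
    trunc_tail_strength = function(p) {
      k <- length(p)
      ps <- sort(p)
      keep <- ps <= tau
      sum(1 - ps[keep] * (k + 1) / seq_len(k)[keep]) / k
    },
    stop("unknown method: ", method)
  )
}

#' Direction in which a combination statistic signals significance
#'
#' @param method statistic name.
#' @return \code{"smaller"} or \code{"larger"}.
#' @export
statDirection <- function(method) {
  switch(method,
    min_p = "smaller", trunc_product = "smaller",
    trunc_tail_strength = "larger",
    stop("unknown method: ", method))
}

#' Null statistics from random groups of consecutive SNPs
#'
#' Draws \code{N} groups of \code{n} consecutive SNPs, each group lying
#' entirely within one chromosome, with start positions uniform over all
#' valid within-chromosome starts, and evaluates the chosen combination
#' statistic on each group's p-values. This is the empirical null that
#' gene-level statistics are calibrated against; it inherits the genome's
#' local p-value structure rather than assuming independence.
#'
#' @param pByChrom named list: per chromosome, the SNP p-values in genome
#'   order.
#' @param n group size (SNPs per group).
#' @param N number of groups.
#' @param method combination statistic (see [statDirection()]).
#' @param tau truncation point for the truncated statistics.
#' @param seed optional; when given, seeds the RNG before sampling.
#' @return numeric vector of N null statistics.
#' @export
sampleNullGroups <- function(pByChrom, n, N,
                             method = c("min_p", "trunc_product",
                                        "trunc_tail_strength"),
                             tau = 0.05, seed = NULL) {
  method <- match.arg(method)
  if (N < 1L) stop("N must be >= 1")
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lens <- vapply(pByChrom, length, integer(1L))
  nStarts <- pmax(0L, lens - n + 1L)
  total <- sum(nStarts)
  if (total == 0L)
    stop("validation error: no chromosome holds ", n, " consecutive SNPs")
  fun <- .statFun(method, tau)
  offsets <- cumsum(c(0L, nStarts[-length(nStarts)]))
  pick <- sample.int(total, N, replace = TRUE)
  chromOf <- findInterval(pick - 1L, cumsum(nStarts), left.open = FALSE) + 1L
  start <- pick - offsets[chromOf]
  out <- numeric(N)
  for (i in seq_len(N)) {
    p <- pByChrom[[chromOf[i]]][start[i]:(start[i] + n - 1L)]
    out[i] <- fun(p)
  }
  out
}

#' Empirical p-value against a null sample
#'
#' \eqn{p = (1 + \#\{null\ at\ least\ as\ significant\}) / (N + 1)}; ties
#' count as at-least-as-significant. The pseudocount bounds the result away
#' from 0 (minimum 1/(N+1)), keeping \code{-log10} finite downstream.
#'
#' @param observed scalar observed statistic.
#' @param nullStats numeric vector of null statistics (nonempty).
#' @param direction \code{"smaller"} if smaller statistics are more
#'   significant, \code{"larger"} otherwise.
#' @return empirical p-value in [1/(N+1), 1].
#' @examples
#' empiricalGeneP(0.3, c(0.1, 0.2, 0.4, 0.5, 0.6), "smaller")  # 0.5
#' @export
empiricalGeneP <- function(observed, nullStats,
                           direction = c("smaller", "larger")) {
  direction <- match.arg(direction)
  if (!length(nullStats)) stop("validation error: empty null sample")
  cnt <- if (direction == "smaller") sum(nullStats <= observed)
         else sum(nullStats >= observed)
  (1 + cnt) / (length(nullStats) + 1)
}

#' Gene-level empirical p-values for one dataset
#'
#' Runs the full gene-scoring procedure: for every gene with at least one
#' mapped SNP, the combination statistic of its SNP p-values is compared to
#' an empirical null of \code{N} random groups of equally many consecutive
#' SNPs. One null sample is drawn per distinct SNP count and shared by all
#' genes with that count, so equal-sized genes are calibrated against the
#' identical reference under a given seed.
#'
#' @param snps SNP data.frame (sorted by chrom, pos) carrying the p-values.
#' @param map a \linkS4class{SnpGeneMap} built from the same SNP set.
#' @param method combination statistic.
#' @param tau truncation point for the truncated statistics.
#' @param N null groups per distinct SNP count (the reference analysis uses
#'   100,000; tests use far fewer).
#' @param seed integer seed for the null sampling.
#' @param datasetId label stored with the result.
#' @return a \linkS4class{GeneScores}.
#' @export
scoreDataset <- function(snps, map, method = c("min_p", "trunc_product",
                                               "trunc_tail_strength"),
                         tau = 0.05, N = 100000L, seed = 1L,
                         datasetId = "dataset") {
  method <- match.arg(method)
  stopifnot(is(map, "SnpGeneMap"))
  ord <- order(snps$chrom, snps$pos_bp)
  snps <- snps[ord, , drop = FALSE]
  if (!identical(as.character(snps$snp_id), map@snpId))
    stop("SNP set of the map does not match the summary statistics")
  .checkP(snps$p_value)
  byGene <- geneSnpIndices(map)
  if (!length(byGene))
    stop("validation error: no SNP mapped to any gene")
  pByChrom <- split(snps$p_value, snps$chrom)
  fun <- .statFun(method, tau)
  direction <- statDirection(method)
  nPerGene <- vapply(byGene, length, integer(1L))
  observed <- vapply(byGene, function(i) fun(snps$p_value[i]), numeric(1L))

  set.seed(seed)
  empirical <- numeric(length(byGene))
  for (n in sort(unique(nPerGene))) {
    nullStats <- sampleNullGroups(pByChrom, n, N, method, tau)
    sel <- which(nPerGene == n)
    empirical[sel] <- vapply(sel, function(i)
      empiricalGeneP(observed[i], nullStats, direction), numeric(1L))
  }
  tab <- data.frame(gene_id = names(byGene), n_snps = nPerGene,
                    raw_stat = observed, empirical_p = empirical,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  new("GeneScores", datasetId = datasetId, table = tab, method = method,
      tau = tau, nullSize = as.integer(N), seed = as.integer(seed))
}

#' @describeIn scoreDataset show method
#' @param object a \linkS4class{GeneScores}.
setMethod("show", "GeneScores", function(object) {
  cat(sprintf("GeneScores for dataset '%s': %d genes\n",
              object@datasetId, nrow(object@table)))
  cat(sprintf("  method: %s (tau = %g), null size N = %d, seed = %d\n",
              object@method, object@tau, object@nullSize, object@seed))
})
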