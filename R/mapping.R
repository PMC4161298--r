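#' Attach genetic coordinates to SNPs
#'
#' @param snps SNP data.frame (see [readSummaryStats()]).
#' @param map a \linkS4class{GeneticMap}.
#' @return \code{snps} with a \code{pos_cm} column added.
#' @export
addGeneticCoords <- function(snps, map) {
  snps$pos_cm <- interpolateCM(map, snps$chrom, snps$pos_bp)
  snps
}

#' Attach genetic coordinates to gene intervals
#'
#' Interpolates cM at both interval ends and records the genetic midpoint
#' (used for overlap tie-breaking and distance pruning).
#'
#' @param genes gene data.frame (see [readGeneAnnotation()]).
#' @param map a \linkS4class{GeneticMap}.
#' @return \code{genes} with \code{start_cm}, \code{end_cm}, \code{mid_cm}.
#' @export
addGeneGeneticCoords <- function(genes, map) {
  genes$start_cm <- interpolateCM(map, genes$chrom, genes$start_bp)
  genes$end_cm <- interpolateCM(map, genes$chrom, genes$end_bp)
  genes$mid_cm <- (genes$start_cm + genes$end_cm) / 2
  genes
}

# Distance from point x to a closed interval [s, e]: 0 inside the body,
# else distance to the nearer boundary.
.pointIntervalDist <- function(x, s, e) pmax(0, pmax(s - x, x - e))

#' Assign SNPs to genes by distance window
#'
#' Each SNP is assigned to the nearest gene within \code{window} of it
#' (distance 0 inside a gene body, else distance to the nearer gene
#' boundary); SNPs farther than the window from every gene are discarded.
#' In \code{genetic} mode distances are in cM over interpolated genetic
#' coordinates; in \code{physical} mode they are in bp.
#'
#' Determinism rules: an exact distance tie between two genes goes to the
#' gene with the smaller start coordinate, then to the lexicographically
#' smaller gene id. A SNP inside two overlapping gene bodies goes to the
#' gene with the nearer midpoint, ties broken the same way.
#'
#' @param snps SNP data.frame, sorted by (chrom, pos_bp); in genetic mode it
#'   must carry \code{pos_cm} (see [addGeneticCoords()]) unless \code{map}
#'   is supplied.
#' @param genes gene data.frame; in genetic mode it must carry
#'   \code{start_cm}/\code{end_cm}/\code{mid_cm} unless \code{map} is given.
#' @param mode \code{"genetic"} (default window 0.01 cM) or
#'   \code{"physical"} (default window 10 kb).
#' @param window assignment window half-width (cM or bp per \code{mode}).
#' @param map optional \linkS4class{GeneticMap} used to interpolate missing
#'   genetic coordinates.
#' @return a \linkS4class{SnpGeneMap} aligned to the rows of \code{snps}.
#' @export
mapSnpsToGenes <- function(snps, genes,
                           mode = c("genetic", "physical"),
                           window = NULL, map = NULL) {
  mode <- match.arg(mode)
  if (is.null(window)) window <- if (mode == "genetic") 0.01 else 10000
  if (window <= 0) stop("window must be positive")
  if (is.unsorted(order(snps$chrom, snps$pos_bp)))
    snps <- snps[order(snps$chrom, snps$pos_bp), , drop = FALSE]

  if (mode == "genetic") {
    if (is.null(snps$pos_cm)) {
      if (is.null(map))
        stop("configuration error: genetic mode requires cM coordinates ",
             "(run addGeneticCoords or pass a genetic map)")
      snps <- addGeneticCoords(snps, map)
    }
    if (is.null(genes$start_cm) || is.null(genes$end_cm)) {
      if (is.null(map))
        stop("configuration error: genetic mode requires gene cM boundaries")
      genes <- addGeneGeneticCoords(genes, map)
    }
    g_start <- genes$start_cm; g_end <- genes$end_cm
    g_mid <- if (!is.null(genes$mid_cm)) genes$mid_cm else (g_start + g_end) / 2
    x_all <- snps$pos_cm
  } else {
    g_start <- genes$start_bp; g_end <- genes$end_bp
    g_mid <- (g_start + g_end) / 2
    x_all <- as.numeric(snps$pos_bp)
  }

  nS <- nrow(snps)
  bestDist <- rep(Inf, nS); bestMid <- rep(Inf, nS)
  bestStart <- rep(Inf, nS); bestId <- rep(NA_character_, nS)

  for (chrom in unique(genes$chrom)) {
    sIdx <- which(snps$chrom == chrom)
    if (!length(sIdx)) next
    x <- x_all[sIdx]
    ord <- order(x)          # within-chromosome ascending coordinate
    xo <- x[ord]
    gIdx <- which(genes$chrom == chrom)
    for (g in gIdx) {
      lo <- findInterval(g_start[g] - window, xo) + 1L
      hi <- findInterval(g_end[g] + window, xo)
      if (lo > hi) next
      cand <- sIdx[ord[lo:hi]]
      d <- .pointIntervalDist(x_all[cand], g_start[g], g_end[g])
      inWin <- d <= window
      if (!any(inWin)) next
      cand <- cand[inWin]; d <- d[inWin]
      dm <- abs(x_all[cand] - g_mid[g])
      # strictly better distance, or tie resolved by (midpoint distance when
      # inside overlapping bodies) then start coordinate then gene id
      better <- d < bestDist[cand] |
        (d == bestDist[cand] & d == 0 & dm < bestMid[cand]) |
        (d == bestDist[cand] & (d > 0 | dm == bestMid[cand]) &
           (g_start[g] < bestStart[cand] |
              (g_start[g] == bestStart[cand] &
                 genes$gene_id[g] < bestId[cand] & !is.na(bestId[cand]))))
      if (any(better)) {
        upd <- cand[better]
        bestDist[upd] <- d[better]; bestMid[upd] <- dm[better]
        bestStart[upd] <- g_start[g]; bestId[upd] <- genes$gene_id[g]
      }
    }
  }
  new("SnpGeneMap", snpId = snps$snp_id, geneId = bestId,
      mode = mode, window = window)
}

#' Per-gene SNP index lists
#'
#' @param map a \linkS4class{SnpGeneMap}.
#' @return named list: for each gene with at least one assigned SNP, the
#'   indices of its SNPs (rows of the SNP table the map was built from),
#'   in genome order.
#' @export
geneSnpIndices <- function(map) {
  stopifnot(is(map, "SnpGeneMap"))
  keep <- !is.na(map@geneId)
  split(which(keep), map@geneId[keep])
}

#' Write a SNP-to-gene audit table
#'
#' Tab-delimited \code{snp_id}, \code{gene_id}; discarded SNPs get ".".
#'
#' @param map a \linkS4class{SnpGeneMap}.
#' @param path output path.
#' @export
writeSnpGeneMap <- function(map, path) {
  out <- data.frame(snp_id = map@snpId,
                    gene_id = ifelse(is.na(map@geneId), ".", map@geneId))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
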