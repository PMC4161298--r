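#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited association table with a header
#' (PLINK \code{.assoc}-style). Column names are mapped through
#' \code{dialect}, so files from other tools can be read by renaming.
#' Rows with missing or non-numeric p-values are dropped with a message;
#' p-values outside (0, 1] are an error (p = 0 would make downstream
#' \code{-log10} infinite and indicates an upstream artifact), naming the
#' offending SNP. Output rows are sorted by (chromosome, position).
#'
#' @param path file path.
#' @param dialect named character vector mapping the internal names
#'   \code{snp_id}, \code{chrom}, \code{pos_bp}, \code{p_value} to the
#'   column names present in the file.
#' @return data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos_bp}, \code{p_value}, sorted by (chrom, pos_bp).
#' @examples
#' f <- tempfile()
#' writeLines(c("SNP\tCHR\tBP\tP", "rs1\t1\t100\t0.5", "rs2\t1\t50\t0.01"), f)
#' readSummaryStats(f)
#' @export
readSummaryStats <- function(path,
                             dialect = c(snp_id = "SNP", chrom = "CHR",
                                         pos_bp = "BP", p_value = "P")) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  need <- c("snp_id", "chrom", "pos_bp", "p_value")
  if (!all(need %in% names(dialect)))
    stop("dialect must map all of: ", paste(need, collapse = ", "))
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  missing_cols <- setdiff(unname(dialect[need]), names(raw))
  if (length(missing_cols))
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  snps <- data.frame(
    snp_id  = as.character(raw[[dialect[["snp_id"]]]]),
    chrom   = as.character(raw[[dialect[["chrom"]]]]),
    pos_bp  = as.integer(raw[[dialect[["pos_bp"]]]]),
    p_value = suppressWarnings(as.numeric(raw[[dialect[["p_value"]]]])),
    stringsAsFactors = FALSE
  )
  bad <- is.na(snps$p_value)
  if (any(bad)) {
    message("discarding ", sum(bad), " row(s) with missing/non-numeric p-value")
    snps <- snps[!bad, , drop = FALSE]
  }
  out_of_range <- snps$p_value <= 0 | snps$p_value > 1
  if (any(out_of_range))
    stop("validation error: p-value outside (0,1] for SNP(s): ",
         paste(head(snps$snp_id[out_of_range], 5L), collapse = ", "))
  if (any(snps$pos_bp < 1L))
    stop("validation error: positions must be >= 1 (1-based coordinates)")
  snps <- snps[order(snps$chrom, snps$pos_bp), , drop = FALSE]
  rownames(snps) <- NULL
  snps
}

#' Write GWAS summary statistics
#'
#' Inverse of [readSummaryStats()] under the default dialect (tab-delimited
#' SNP/CHR/BP/P with header).
#'
#' @param snps data.frame as returned by [readSummaryStats()].
#' @param path output path.
#' @export
writeSummaryStats <- function(snps, path) {
  out <- data.frame(SNP = snps$snp_id, CHR = snps$chrom,
                    BP = snps$pos_bp, P = snps$p_value)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation intervals
#'
#' Reads a BED-like four-column file (chrom, start, end, gene id; no header;
#' 0-based half-open intervals as in BED) and converts to the 1-based closed
#' intervals used internally.
#'
#' @param path file path.
#' @return data.frame with \code{gene_id}, \code{chrom}, \code{start_bp},
#'   \code{end_bp} (1-based, closed).
#' @export
readGeneAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 4L)
    stop("format error: expected BED-like columns chrom, start, end, gene_id")
  genes <- data.frame(
    gene_id  = as.character(raw[[4L]]),
    chrom    = as.character(raw[[1L]]),
    start_bp = as.integer(raw[[2L]]) + 1L,
    end_bp   = as.integer(raw[[3L]]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id))
    stop("validation error: duplicate gene ids in annotation")
  if (any(genes$start_bp > genes$end_bp))
    stop("validation error: interval start after end")
  genes[order(genes$chrom, genes$start_bp), , drop = FALSE]
}

#' @rdname readGeneAnnotation
#' @param genes data.frame with \code{gene_id}, \code{chrom},
#'   \code{start_bp}, \code{end_bp} (1-based closed; written back as 0-based
#'   half-open BED).
#' @export
writeGeneAnnotation <- function(genes, path) {
  out <- data.frame(genes$chrom, genes$start_bp - 1L, genes$end_bp,
                    genes$gene_id)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a recombination map
#'
#' Accepts the HapMap/Oxford three-column style (position, rate, cumulative
#' cM; header present; the rate column is ignored) for a single chromosome
#' named via \code{chrom}, or a four-column variant with a leading
#' chromosome column covering several chromosomes at once.
#'
#' @param path file path.
#' @param chrom chromosome label, required for three-column single-chromosome
#'   files.
#' @return a \linkS4class{GeneticMap}.
#' @export
readGeneticMap <- function(path, chrom = NULL) {
  if (!file.exists(path)) stop("genetic-map file not found: ", path)
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(raw) >= 4L) {
    parts <- split(raw, as.character(raw[[1L]]))
    maps <- lapply(parts, function(p)
      data.frame(pos_bp = as.numeric(p[[2L]]), cm = as.numeric(p[[4L]])))
  } else if (ncol(raw) == 3L) {
    if (is.null(chrom))
      stop("three-column map: supply the chromosome label via 'chrom'")
    maps <- setNames(
      list(data.frame(pos_bp = as.numeric(raw[[1L]]), cm = as.numeric(raw[[3L]]))),
      chrom)
  } else stop("format error: expected 3 (pos, rate, cM) or 4 (chrom, ...) columns")
  maps <- lapply(maps, function(m) m[order(m$pos_bp), , drop = FALSE])
  for (nm in names(maps))
    if (is.unsorted(maps[[nm]]$cm))
      stop("format error: decreasing cumulative cM on chromosome ", nm)
  new("GeneticMap", maps = maps)
}

#' Interpolate genetic position
#'
#' Linear interpolation of cumulative cM at physical positions; queries
#' outside the mapped range clamp to the boundary cM value.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param chrom chromosome label (scalar, or vector parallel to
#'   \code{pos_bp}).
#' @param pos_bp physical positions (bp) to interpolate at.
#' @return numeric vector of cM positions.
#' @examples
#' m <- new("GeneticMap",
#'          maps = list("1" = data.frame(pos_bp = c(1000, 2000), cm = c(0, 1))))
#' interpolateCM(m, "1", c(500, 1500, 3000))   # 0.0 0.5 1.0
#' @export
interpolateCM <- function(map, chrom, pos_bp) {
  stopifnot(is(map, "GeneticMap"))
  chrom <- as.character(chrom)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos_bp))
  if (length(chrom) != length(pos_bp))
    stop("chrom must be scalar or parallel to pos_bp")
  out <- numeric(length(pos_bp))
  for (c_ in unique(chrom)) {
    m <- map@maps[[c_]]
    if (is.null(m)) stop("chromosome not in genetic map: ", c_)
    idx <- chrom == c_
    if (nrow(m) == 1L) {
      out[idx] <- m$cm
    } else {
      out[idx] <- approx(m$pos_bp, m$cm, xout = pos_bp[idx], rule = 2,
                         ties = "ordered")$y
    }
  }
  out
}

#' Read a study covariate table
#'
#' Tab-delimited with header: \code{dataset_id}, \code{array},
#' \code{method}, \code{n} (sample size).
#'
#' @param path file path.
#' @return data.frame with \code{dataset_id}, \code{array_label},
#'   \code{method_label}, \code{sample_size}.
#' @export
readCovariates <- function(path) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE, sep = "\t")
  need <- c("dataset_id", "array", "method", "n")
  if (!all(need %in% names(raw)))
    stop("format error: covariate table needs columns: ",
         paste(need, collapse = ", "))
  cov <- data.frame(
    dataset_id   = as.character(raw$dataset_id),
    array_label  = as.character(raw$array),
    method_label = as.character(raw$method),
    sample_size  = as.integer(raw$n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(cov$dataset_id))
    stop("validation error: duplicate dataset_id in covariate table")
  if (any(cov$sample_size <= 0L))
    stop("validation error: sample sizes must be positive")
  cov
}

#' @rdname readCovariates
#' @param cov covariate data.frame (internal column names).
#' @export
writeCovariates <- function(cov, path) {
  out <- data.frame(dataset_id = cov$dataset_id, array = cov$array_label,
                    method = cov$method_label, n = cov$sample_size)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a pre-ranked gene list (.rnk)
#'
#' Two-column, tab-delimited, headerless (gene, score), sorted by descending
#' score — the input format of pre-ranked gene-set enrichment tools.
#'
#' @param geneIds character vector of gene ids (no duplicates).
#' @param scores numeric, one score per gene.
#' @param path output path.
#' @export
writeRnk <- function(geneIds, scores, path) {
  if (length(geneIds) != length(scores))
    stop("one score per gene required")
  if (anyDuplicated(geneIds))
    stop("validation error: duplicate gene ids")
  ord <- order(scores, decreasing = TRUE)
  out <- data.frame(geneIds[ord], scores[ord])
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeRnk
#' @return \code{readRnk}: data.frame with \code{gene_id}, \code{score}.
#' @export
readRnk <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(gene_id = character(), score = numeric()))
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE, sep = "\t")
  data.frame(gene_id = as.character(raw[[1L]]), score = as.numeric(raw[[2L]]))
}

#' Persist gene-level scores
#'
#' Tab-delimited with header and the scoring metadata (method, tau, null
#' size, seed) repeated per row so files are self-describing.
#'
#' @param gs a \linkS4class{GeneScores}.
#' @param path output path.
#' @export
writeGeneScores <- function(gs, path) {
  stopifnot(is(gs, "GeneScores"))
  tab <- gs@table
  out <- data.frame(dataset_id = gs@datasetId, tab,
                    method = gs@method, tau = gs@tau,
                    null_size = gs@nullSize, seed = gs@seed)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneScores
#' @return \code{readGeneScores}: a \linkS4class{GeneScores}.
#' @export
readGeneScores <- function(path) {
  if (!file.exists(path)) stop("gene-score file not found: ", path)
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE, sep = "\t")
  need <- c("dataset_id", "gene_id", "n_snps", "raw_stat", "empirical_p",
            "method", "tau", "null_size", "seed")
  if (!all(need %in% names(raw)))
    stop("format error: gene-score table needs columns: ",
         paste(need, collapse = ", "))
  if (length(unique(raw$dataset_id)) != 1L)
    stop("gene-score file must describe a single dataset")
  new("GeneScores",
      datasetId = raw$dataset_id[1L],
      table = data.frame(gene_id = as.character(raw$gene_id),
                         n_snps = as.integer(raw$n_snps),
                         raw_stat = raw$raw_stat,
                         empirical_p = raw$empirical_p,
                         stringsAsFactors = FALSE),
      method = raw$method[1L], tau = raw$tau[1L],
      nullSize = as.integer(raw$null_size[1L]),
      seed = as.integer(raw$seed[1L]))
}

#' Persist / load a score matrix
#'
#' The matrix is written genes-as-columns with a leading \code{dataset_id}
#' column; covariates go to a sidecar table next to it.
#'
#' @param sm a \linkS4class{ScoreMatrix}.
#' @param path output path for the matrix; the covariate sidecar is written
#'   to \code{paste0(path, ".covariates.tsv")}.
#' @export
writeScoreMatrix <- function(sm, path) {
  stopifnot(is(sm, "ScoreMatrix"))
  Z <- scoreMatrix(sm)
  out <- data.frame(dataset_id = rownames(Z), Z, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeCovariates(covariates(sm), paste0(path, ".covariates.tsv"))
  invisible(path)
}

#' @rdname writeScoreMatrix
#' @export
readScoreMatrix <- function(path) {
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    sep = "\t", check.names = FALSE)
  cov <- readCovariates(paste0(path, ".covariates.tsv"))
  Z <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(Z) <- raw$dataset_id
  cov <- cov[match(rownames(Z), cov$dataset_id), , drop = FALSE]
  .newScoreMatrix(Z, cov)
}
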