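#' Construct a pleiotropy simulation design
#'
#' @param nPerClass diseases per class (default 5; classes are labelled
#'   A1..A5 and B1..B5).
#' @param nGenes total genes (default 10000).
#' @param set2Size genes with p ~ U(0, pSignal) in every class-A disease
#'   (class-wide pleiotropy; default 40).
#' @param set3Size genes with p ~ U(0, pSignal) in A1, A2, B1, B2 only
#'   (cross-class pleiotropy; default 40).
#' @param pSignal upper bound of the signal p-value distribution
#'   (default 0.05, i.e. nominally significant draws).
#' @return a \linkS4class{SimulationDesign}.
#' @export
simulationDesign <- function(nPerClass = 5L, nGenes = 10000L,
                             set2Size = 40L, set3Size = 40L,
                             pSignal = 0.05) {
  new("SimulationDesign", nPerClass = as.integer(nPerClass),
      nGenes = as.integer(nGenes), set2Size = as.integer(set2Size),
      set3Size = as.integer(set3Size), pSignal = pSignal)
}

setMethod("show", "SimulationDesign", function(object) {
  cat(sprintf(
    "SimulationDesign: 2 x %d diseases, %d genes; class-A set %d, quartet set %d, signal U(0,%g)\n",
    object@nPerClass, object@nGenes, object@set2Size, object@set3Size,
    object@pSignal))
})

#' Disease labels of a design
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @return character vector A1..An, B1..Bn.
#' @export
diseaseLabels <- function(design) {
  n <- design@nPerClass
  c(paste0("A", seq_len(n)), paste0("B", seq_len(n)))
}

#' Expected dataset grouping under a design
#'
#' The four groups that a correct clustering of the simulated diseases must
#' reproduce: the two cross-class pleiotropic pairs (A1, A2) and (B1, B2),
#' and the remaining diseases of each class.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @return list of four character vectors.
#' @export
expectedGrouping <- function(design) {
  n <- design@nPerClass
  stopifnot(n >= 3L)
  list(c("A1", "A2"), c("B1", "B2"),
       paste0("A", 3:n), paste0("B", 3:n))
}

#' Simulate the pleiotropy gene p-value matrix
#'
#' Draws the disease-by-gene p-value matrix directly at the gene level:
#' background genes are U(0,1) in every disease; the class-A set is
#' U(0, pSignal) in all class-A diseases (and U(0,1) in class B); the
#' quartet set is U(0, pSignal) in A1, A2, B1, B2 (and U(0,1) elsewhere).
#' All draws are independent across diseases and genes.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param seed integer seed (draws are reproducible given the seed).
#' @return list with \code{p} (disease x gene p-value matrix, dimnames
#'   set), \code{truth} (factor per gene: \code{background},
#'   \code{class_A_set}, \code{quartet_set}) and \code{design}.
#' @export
simulatePleiotropyMatrix <- function(design = simulationDesign(),
                                     seed = NULL) {
  stopifnot(is(design, "SimulationDesign"))
  validObject(design)
  if (!is.null(seed)) set.seed(seed)
  n <- design@nPerClass; g <- design@nGenes
  d <- 2L * n
  labels <- diseaseLabels(design)
  P <- matrix(runif(d * g), d, g,
              dimnames = list(labels, sprintf("g%05d", seq_len(g))))
  s2 <- design@set2Size; s3 <- design@set3Size
  truth <- factor(rep("background", g),
                  levels = c("background", "class_A_set", "quartet_set"))
  if (s2 > 0L) {
    cols <- seq_len(s2)
    P[seq_len(n), cols] <- runif(n * s2, 0, design@pSignal)
    truth[cols] <- "class_A_set"
  }
  if (s3 > 0L) {
    cols <- s2 + seq_len(s3)
    quartet <- c(1L, 2L, n + 1L, n + 2L)
    P[quartet, cols] <- runif(4L * s3, 0, design@pSignal)
    truth[cols] <- "quartet_set"
  }
  list(p = P, truth = truth, design = design)
}

#' Single-replicate recovery check
#'
#' Runs the analysis pipeline on one simulated matrix (-log10, column
#' centering, SVD; no covariates), clusters the diseases by complete-linkage
#' Euclidean distance on the first two principal components, and asks
#' whether the four planted groups are recovered exactly at the
#' four-cluster cut.
#'
#' @param sim result of [simulatePleiotropyMatrix()].
#' @param linkage linkage passed to [hierarchicalCluster()].
#' @param nPcs leading components used for the distances (default 2).
#' @return logical.
#' @export
recoveryCheck <- function(sim, linkage = "complete", nPcs = 2L) {
  pca <- runPCA(-log10(sim$p))
  tree <- hierarchicalCluster(pcDistances(pca, nPcs), linkage, nPcs = nPcs)
  groupingCorrect(tree, expectedGrouping(sim$design))
}

#' Recovery rate of the planted disease grouping
#'
#' Fraction of simulation replicates in which the pipeline recovers the
#' planted grouping (see [recoveryCheck()]), with both pleiotropic gene
#' sets at the given size.
#'
#' @param setSize genes per pleiotropic set (applied to both sets).
#' @param nReps replicates (default 50).
#' @param seed seed for the replicate stream.
#' @param design base design; its set sizes are overridden by
#'   \code{setSize}.
#' @param linkage,nPcs passed to [recoveryCheck()].
#' @return success fraction in [0, 1].
#' @export
recoveryRate <- function(setSize, nReps = 50L, seed = 1L,
                         design = simulationDesign(),
                         linkage = "complete", nPcs = 2L) {
  stopifnot(nReps >= 1L)
  design <- simulationDesign(design@nPerClass, design@nGenes,
                             setSize, setSize, design@pSignal)
  set.seed(seed)
  ok <- vapply(seq_len(nReps), function(r)
    recoveryCheck(simulatePleiotropyMatrix(design), linkage, nPcs),
    logical(1L))
  mean(ok)
}

#' Simulate SNP-level GWAS summary statistics
#'
#' End-to-end synthetic inputs for the full pipeline: evenly spaced SNP
#' grids on a few chromosomes, a linear genetic map, non-overlapping gene
#' intervals, and per-dataset SNP p-values that are U(0,1) genome-wide
#' except over planted associated genes, whose SNPs draw p ~ U(0, pMax).
#' The default pMax of 0.01 emulates the tag-SNP p-values of a true locus
#' in a moderately powered study. When \code{dir} is given, all gwas-io
#' formats are written there (per-dataset summary statistics, BED gene
#' annotation, 4-column genetic map, covariate table, truth table).
#'
#' @param nChrom chromosomes.
#' @param snpsPerChrom SNPs per chromosome (evenly spaced).
#' @param genesPerChrom genes per chromosome (evenly spaced intervals).
#' @param nDatasets GWAS datasets to simulate.
#' @param plantedPerDataset associated genes planted per dataset (drawn at
#'   random per dataset).
#' @param sharedPlanted optional character vector of gene ids planted in
#'   every dataset (pleiotropic genes), in addition to the random ones.
#' @param pMax upper bound for p-values of SNPs in planted genes.
#' @param bpSpacing physical spacing between adjacent SNPs (bp).
#' @param cmPerMb genetic map slope (cM per Mb; default 1).
#' @param seed integer seed.
#' @param dir optional output directory; created if needed.
#' @return list with \code{snps} (list of per-dataset SNP data.frames),
#'   \code{genes}, \code{map} (a \linkS4class{GeneticMap}),
#'   \code{covariates}, \code{planted} (per-dataset gene ids), and, when
#'   \code{dir} is given, \code{paths}.
#' @export
simulateSnpLevel <- function(nChrom = 2L, snpsPerChrom = 500L,
                             genesPerChrom = 10L, nDatasets = 4L,
                             plantedPerDataset = 3L, sharedPlanted = NULL,
                             pMax = 0.01, bpSpacing = 5000L, cmPerMb = 1,
                             seed = 1L, dir = NULL) {
  set.seed(seed)
  chroms <- as.character(seq_len(nChrom))
  span <- snpsPerChrom * bpSpacing

  snpGrid <- do.call(rbind, lapply(chroms, function(c_) data.frame(
    snp_id = sprintf("rs%s_%04d", c_, seq_len(snpsPerChrom)),
    chrom = c_, pos_bp = bpSpacing * seq_len(snpsPerChrom),
    stringsAsFactors = FALSE)))

  geneLen <- max(bpSpacing * 4L, span %/% (4L * genesPerChrom))
  gap <- (span - genesPerChrom * geneLen) %/% (genesPerChrom + 1L)
  genes <- do.call(rbind, lapply(chroms, function(c_) {
    start <- gap + (seq_len(genesPerChrom) - 1L) * (geneLen + gap) + 1L
    data.frame(gene_id = sprintf("GENE%s_%02d", c_, seq_len(genesPerChrom)),
               chrom = c_, start_bp = as.integer(start),
               end_bp = as.integer(start + geneLen - 1L),
               stringsAsFactors = FALSE)
  }))

  maps <- setNames(lapply(chroms, function(c_)
    data.frame(pos_bp = c(1, span), cm = c(0, span * 1e-6 * cmPerMb))),
    chroms)
  map <- new("GeneticMap", maps = maps)

  datasetIds <- sprintf("study%02d", seq_len(nDatasets))
  planted <- list(); snpsByDataset <- list()
  for (ds in datasetIds) {
    pl <- unique(c(sharedPlanted,
                   sample(genes$gene_id, plantedPerDataset)))
    planted[[ds]] <- pl
    p <- runif(nrow(snpGrid))
    for (g in pl) {
      gi <- genes[genes$gene_id == g, ]
      hit <- snpGrid$chrom == gi$chrom &
        snpGrid$pos_bp >= gi$start_bp & snpGrid$pos_bp <= gi$end_bp
      p[hit] <- runif(sum(hit), 0, pMax)
    }
    p <- pmax(p, .Machine$double.eps)   # keep within (0,1]
    snpsByDataset[[ds]] <- data.frame(snpGrid, p_value = p,
                                      stringsAsFactors = FALSE)
  }

  covariates <- data.frame(
    dataset_id = datasetIds,
    array_label = rep(c("chip_alpha", "chip_beta"),
                      length.out = nDatasets),
    method_label = rep(c("logistic", "logistic", "trend"),
                       length.out = nDatasets),
    sample_size = as.integer(round(runif(nDatasets, 2000, 8000))),
    stringsAsFactors = FALSE)

  out <- list(snps = snpsByDataset, genes = genes, map = map,
              covariates = covariates, planted = planted)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genes = file.path(dir, "genes.bed"),
      map = file.path(dir, "genetic_map.tsv"),
      covariates = file.path(dir, "covariates.tsv"),
      truth = file.path(dir, "planted_genes.tsv"))
    writeGeneAnnotation(genes, paths$genes)
    mapTab <- do.call(rbind, lapply(chroms, function(c_) data.frame(
      chrom = c_, position = maps[[c_]]$pos_bp,
      rate_cM_Mb = cmPerMb, cM = maps[[c_]]$cm)))
    write.table(mapTab, paths$map, sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeCovariates(covariates, paths$covariates)
    truth <- do.call(rbind, lapply(datasetIds, function(ds) data.frame(
      dataset_id = ds, gene_id = planted[[ds]], stringsAsFactors = FALSE)))
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (ds in datasetIds) {
      paths[[paste0("assoc_", ds)]] <- file.path(dir, paste0(ds, ".assoc"))
      writeSummaryStats(snpsByDataset[[ds]], paths[[paste0("assoc_", ds)]])
    }
    out$paths <- paths
  }
  out
}
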