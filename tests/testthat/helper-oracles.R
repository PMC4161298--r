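# Independent brute-force oracles used to cross-check the package's
# algorithmic paths. These deliberately share no code with R/.

# All-pairs nearest-gene-within-window assignment with the package's
# tie-break contract: distance, then (inside overlapping bodies) midpoint
# distance, then start coordinate, then gene id.
oracleMapSnps <- function(snps, genes, mode, window) {
  if (mode == "genetic") {
    x <- snps$pos_cm; gs <- genes$start_cm; ge <- genes$end_cm
  } else {
    x <- as.numeric(snps$pos_bp); gs <- genes$start_bp; ge <- genes$end_bp
  }
  gm <- (gs + ge) / 2
  out <- rep(NA_character_, nrow(snps))
  for (i in seq_len(nrow(snps))) {
    best <- NULL
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] != snps$chrom[i]) next
      d <- max(0, gs[g] - x[i], x[i] - ge[g])
      if (d > window) next
      cand <- list(d = d, mid = abs(x[i] - gm[g]),
                   start = gs[g], id = genes$gene_id[g])
      if (is.null(best)) { best <- cand; next }
      takes <- if (cand$d != best$d) cand$d < best$d
        else if (cand$d == 0 && cand$mid != best$mid) cand$mid < best$mid
        else if (cand$start != best$start) cand$start < best$start
        else cand$id < best$id
      if (takes) best <- cand
    }
    if (!is.null(best)) out[i] <- best$id
  }
  out
}

# Counting definition of the empirical p-value.
oracleEmpiricalP <- function(observed, nullStats, direction) {
  cnt <- 0L
  for (s in nullStats) {
    hit <- if (direction == "smaller") s <= observed else s >= observed
    if (hit) cnt <- cnt + 1L
  }
  (1 + cnt) / (length(nullStats) + 1)
}

# O(n^3) agglomerative clustering. Returns the sequence of merge heights and
# the partition (canonical strings) after each merge.
oracleAgglomerate <- function(D, linkage = "complete") {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  linkFun <- switch(linkage, complete = max, single = min, average = mean)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    bestD <- Inf; bi <- bj <- NA
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dij <- linkFun(D[clusters[[i]], clusters[[j]]])
      if (dij < bestD) { bestD <- dij; bi <- i; bj <- j }
    }
    merged <- c(clusters[[bi]], clusters[[bj]])
    clusters <- c(clusters[-c(bi, bj)], list(merged))
    heights <- c(heights, bestD)
    partitions[[length(partitions) + 1L]] <-
      canonicalPartition(lapply(clusters, identity))
  }
  list(heights = heights, partitions = partitions)
}

canonicalPartition <- function(groups) {
  sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
              character(1L), USE.NAMES = FALSE))
}

# Partition sequence of an hclust tree, outside-in, matching
# oracleAgglomerate's reporting (state after each merge).
hclustPartitions <- function(hc) {
  n <- length(hc$order)
  lapply((n - 1L):1L, function(k) {
    ct <- cutree(hc, k)
    canonicalPartition(split(seq_len(n), ct))
  })
}

# Small random SNP/gene instance on a handful of chromosomes, with both
# physical and genetic coordinates (arbitrary monotone cM).
randomMapInstance <- function(nSnps = 200L, nGenes = 10L, nChrom = 2L) {
  chroms <- as.character(seq_len(nChrom))
  snps <- data.frame(
    snp_id = sprintf("s%03d", seq_len(nSnps)),
    chrom = sample(chroms, nSnps, replace = TRUE),
    pos_bp = sample.int(1000000L, nSnps),
    p_value = runif(nSnps),
    stringsAsFactors = FALSE)
  snps <- snps[order(snps$chrom, snps$pos_bp), ]
  snps$pos_cm <- snps$pos_bp * 1e-6 * 1.3
  starts <- sample.int(900000L, nGenes)
  genes <- data.frame(
    gene_id = sprintf("g%02d", seq_len(nGenes)),
    chrom = sample(chroms, nGenes, replace = TRUE),
    start_bp = starts,
    end_bp = starts + sample.int(80000L, nGenes),
    stringsAsFactors = FALSE)
  genes$start_cm <- genes$start_bp * 1e-6 * 1.3
  genes$end_cm <- genes$end_bp * 1e-6 * 1.3
  genes$mid_cm <- (genes$start_cm + genes$end_cm) / 2
  list(snps = snps, genes = genes)
}

# Synthetic GeneScores table with given empirical p-values (null size set
# high enough that any p in (0,1] is admissible).
makeGeneScores <- function(datasetId, geneIds, p,
                           nSnps = rep(5L, length(geneIds))) {
  new("GeneScores", datasetId = datasetId,
      table = data.frame(gene_id = geneIds, n_snps = nSnps,
                         raw_stat = p, empirical_p = p,
                         stringsAsFactors = FALSE),
      method = "min_p", tau = 0.05, nullSize = 10000000L, seed = 1L)
}

# Covariate table with three informative columns (binary array, binary
# method, varying sample size).
makeCovariates <- function(ids) {
  n <- length(ids)
  data.frame(
    dataset_id = ids,
    array_label = rep(c("arrA", "arrB"), length.out = n),
    method_label = rep(c("m1", "m1", "m2"), length.out = n),
    sample_size = as.integer(seq(1000, 9000, length.out = n)),
    stringsAsFactors = FALSE)
}
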