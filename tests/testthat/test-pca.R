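test_that("score matrix assembly intersects genes and takes -log10", {
  t1 <- makeGeneScores("d1", c("A", "B", "C"), c(0.01, 0.1, 0.5))
  t2 <- makeGeneScores("d2", c("B", "C", "D"), c(0.2, 0.02, 0.9))
  sm <- buildScoreMatrix(list(t1, t2), makeCovariates(c("d1", "d2")))
  expect_equal(geneIds(sm), c("B", "C"))
  expect_equal(datasetIds(sm), c("d1", "d2"))
  Z <- scoreMatrix(sm)
  expect_equal(unname(Z),
               -log10(rbind(c(0.1, 0.5), c(0.2, 0.02))))
  expect_equal(Z["d1", "B"], 1.0)   # empirical p 0.1 -> 1
  expect_equal(unname(scoreMatrix(sm)["d2", "C"]), -log10(0.02))

  t3 <- makeGeneScores("d3", c("X", "Y"), c(0.5, 0.5))
  expect_error(buildScoreMatrix(list(t1, t3),
                                makeCovariates(c("d1", "d3"))),
               "no gene is shared")
  expect_error(buildScoreMatrix(list(t1, t2), makeCovariates("d1")),
               "missing from the covariate table")
})

test_that("column centering removes exactly the column means", {
  expect_equal(centerColumns(matrix(c(1, 3), 2, 1)),
               matrix(c(-1, 1), 2, 1))
  expect_equal(centerColumns(matrix(5, 4, 2)), matrix(0, 4, 2))
  set.seed(2)
  B <- centerColumns(matrix(rnorm(35), 5, 7))
  expect_true(all(abs(colSums(B)) < 1e-12))
})

test_that("confounder regression matches closed-form OLS", {
  # 6 datasets, single informative covariate (sample size)
  ids <- paste0("d", 1:6)
  cov <- data.frame(dataset_id = ids, array_label = "a",
                    method_label = "m",
                    sample_size = c(1000L, 2000L, 3000L, 5000L, 7000L, 9000L))
  x <- log10(cov$sample_size)
  set.seed(4)
  Z <- cbind(2 + 3 * x + rnorm(6, sd = 0.1), rnorm(6))
  dimnames(Z) <- list(ids, c("gSig", "gNoise"))
  sm <- disPCA:::.newScoreMatrix(abs(Z), cov)
  Zs <- scoreMatrix(sm)
  rep <- testConfounders(sm)
  tab <- rep@table
  slope <- function(z) sum((x - mean(x)) * (z - mean(z))) /
    sum((x - mean(x))^2)
  expect_equal(tab$estimate[tab$gene_id == "gSig"],
               slope(Zs[, "gSig"]), tolerance = 1e-10)
  expect_lt(tab$p_value[tab$gene_id == "gSig"],
            tab$p_value[tab$gene_id == "gNoise"])
})

test_that("a gene equal to a covariate is the most significant gene", {
  ids <- paste0("d", 1:8)
  cov <- makeCovariates(ids)
  X <- disPCA:::.designMatrix(cov)
  set.seed(5)
  Z <- matrix(abs(rnorm(8 * 20)), 8, 20,
              dimnames = list(ids, sprintf("g%02d", 1:20)))
  Z[, 1] <- X[, "array_labelarrB"] * 2 + 0.5   # exact covariate image
  sm <- disPCA:::.newScoreMatrix(Z, cov)
  tab <- testConfounders(sm)@table
  arr <- tab[tab$covariate == "array_labelarrB", ]
  expect_equal(arr$gene_id[which.min(arr$p_value)], "g01")
})

test_that("noise genes are almost never flagged after Bonferroni", {
  ids <- paste0("d", 1:10)
  cov <- makeCovariates(ids)
  set.seed(6)
  flagged <- replicate(20, {
    Z <- matrix(abs(rnorm(10 * 50)), 10, 50,
                dimnames = list(ids, sprintf("g%02d", 1:50)))
    sum(testConfounders(disPCA:::.newScoreMatrix(Z, cov))@table$significant)
  })
  # family-wise over 3 covariate columns: any-flag probability ~ 3 * alpha
  expect_lt(mean(flagged > 0), 0.4)
})

test_that("rank-deficient covariate designs are rejected with names", {
  ids <- paste0("d", 1:6)
  cov <- makeCovariates(ids)
  cov$method_label <- cov$array_label   # collinear encoding
  Z <- matrix(abs(rnorm(6 * 5)), 6, 5, dimnames = list(ids, paste0("g", 1:5)))
  expect_error(testConfounders(disPCA:::.newScoreMatrix(Z, cov)),
               "collinear")
})

test_that("residualization projects out the covariate design", {
  ids <- paste0("d", 1:9)
  cov <- makeCovariates(ids)
  X <- disPCA:::.designMatrix(cov)
  set.seed(7)
  Z <- matrix(abs(rnorm(9 * 30)), 9, 30)
  rownames(Z) <- ids

  # oracle: hat-matrix projection
  H <- X %*% solve(crossprod(X)) %*% t(X)
  expect_equal(residualize(Z, covariates = cov),
               (diag(9) - H) %*% Z, ignore_attr = TRUE, tolerance = 1e-10)

  # residual columns orthogonal to every design column
  R <- residualize(Z, covariates = cov)
  expect_lt(max(abs(crossprod(X, R))), 1e-8)

  # a gene equal to a design column residualizes to zero
  Z2 <- Z; Z2[, 1] <- X[, 2]
  expect_lt(max(abs(residualize(Z2, covariates = cov)[, 1])), 1e-10)

  # intercept-only covariates reduce to column centering
  cov0 <- data.frame(dataset_id = ids, array_label = "a",
                     method_label = "m", sample_size = 5000L)
  expect_equal(residualize(Z, covariates = cov0), centerColumns(Z))
})

test_that("PCA matches the 2x2 closed form and the eigen identity", {
  r <- runPCA(matrix(c(-1, 1, -1, 1), 2, 2))
  expect_equal(sqrt(eigenvalues(r)), c(2, 0))
  expect_equal(varianceFractions(r)[1], 1.0)

  set.seed(9)
  for (i in 1:50) {
    d <- sample(3:8, 1); g <- sample(4:40, 1)
    M <- matrix(rnorm(d * g), d, g)
    r <- runPCA(M)
    B <- centerColumns(M)
    evOracle <- eigen(B %*% t(B), symmetric = TRUE,
                      only.values = TRUE)$values
    k <- length(eigenvalues(r))
    expect_equal(eigenvalues(r), evOracle[seq_len(k)], tolerance = 1e-8)
  }
})

test_that("coordinates equal centered matrix times loadings", {
  set.seed(10)
  M <- matrix(rnorm(8 * 50), 8, 50)
  r <- runPCA(M)
  expect_equal(datasetCoords(r),
               centerColumns(M) %*% geneLoadings(r),
               ignore_attr = TRUE, tolerance = 1e-8)
  # loadings orthonormal
  G <- crossprod(geneLoadings(r))
  expect_equal(G, diag(ncol(G)), ignore_attr = TRUE, tolerance = 1e-8)
  # variance fractions are a nonincreasing probability vector
  vf <- varianceFractions(r)
  expect_equal(sum(vf), 1)
  expect_true(all(diff(vf) <= 1e-12) && all(vf >= 0))
})

test_that("PCA is invariant to row permutation up to reordered coordinates", {
  set.seed(11)
  M <- matrix(rnorm(6 * 30), 6, 30, dimnames = list(paste0("d", 1:6), NULL))
  perm <- sample(6)
  r1 <- runPCA(M)
  r2 <- runPCA(M[perm, ])
  expect_equal(eigenvalues(r1), eigenvalues(r2), tolerance = 1e-8)
  # null-space components (zero eigenvalue) carry arbitrary directions
  nz <- which(eigenvalues(r1) > 1e-8 * eigenvalues(r1)[1])
  expect_equal(geneLoadings(r2)[, nz], geneLoadings(r1)[, nz],
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(datasetCoords(r2)[, nz], datasetCoords(r1)[perm, nz],
               tolerance = 1e-6)
})

test_that("residualizing c covariate columns zeroes exactly c extra components", {
  ids <- paste0("d", 1:10)
  cov <- makeCovariates(ids)    # 3 encoded columns
  set.seed(12)
  Z <- matrix(abs(rnorm(10 * 200)), 10, 200)
  rownames(Z) <- ids
  evRaw <- eigenvalues(runPCA(Z))
  evRes <- eigenvalues(runPCA(residualize(Z, covariates = cov)))
  nzero <- function(ev) sum(ev < 1e-10 * ev[1])
  expect_equal(nzero(evRaw), 1L)    # centering alone
  expect_equal(nzero(evRes), 4L)    # centering + 3 covariate columns
})

test_that("top-loading genes rank by mean absolute loading", {
  loadings <- cbind(PC1 = c(A = 0.9, B = -0.95, C = 0.1))
  pca <- new("PcaResult", coords = matrix(0, 2, 1), pcs = matrix(0, 2, 1),
             loadings = loadings, eigenvalues = 1,
             varianceFraction = 1, source = "raw")
  expect_equal(topLoadingGenes(pca, 1, 2)$gene_id, c("B", "A"))
  expect_equal(nrow(topLoadingGenes(pca, 1, 10)), 3L)

  set.seed(13)
  L <- matrix(rnorm(60), 30, 2,
              dimnames = list(sprintf("g%02d", 1:30), c("PC1", "PC2")))
  pca2 <- new("PcaResult", coords = matrix(0, 5, 2), pcs = matrix(0, 5, 2),
              loadings = L, eigenvalues = c(2, 1),
              varianceFraction = c(2, 1) / 3, source = "raw")
  got <- topLoadingGenes(pca2, 1:2, 10)$gene_id
  score <- rowMeans(abs(L))
  expect_equal(got, names(sort(score, decreasing = TRUE))[1:10])
})

test_that("distance pruning drops the latter of nearby gene pairs", {
  g <- function(cm) data.frame(gene_id = sprintf("g%d", seq_along(cm)),
                               chrom = "1", cm = cm)
  expect_equal(pruneByDistance(g(c(1.00, 1.05, 1.20)), 0.1)$cm, c(1.00, 1.20))
  expect_equal(pruneByDistance(g(c(1.0, 2.0, 3.0)), 0.1)$cm, c(1, 2, 3))
  # chained: 1.08 dropped against 1.00; 1.15 kept (0.15 from last retained)
  expect_equal(pruneByDistance(g(c(1.00, 1.08, 1.15)), 0.1)$cm, c(1.00, 1.15))
  # different chromosomes never conflict
  two <- data.frame(gene_id = c("a", "b"), chrom = c("1", "2"),
                    cm = c(1.0, 1.01))
  expect_equal(nrow(pruneByDistance(two, 0.1)), 2L)
  expect_error(pruneByDistance(data.frame(gene_id = "a", chrom = "1",
                                          cm = NA_real_)), "missing cM")
})

test_that("loading correlation is sign-invariant and t-p matches permutation", {
  set.seed(14)
  M <- matrix(rnorm(8 * 100), 8, 100,
              dimnames = list(paste0("d", 1:8), sprintf("g%03d", 1:100)))
  pca <- runPCA(M)
  self <- correlateLoadings(pca, pca, 1:2, 50)
  expect_equal(self$r, 1.0, tolerance = 1e-12)

  flipped <- pca
  flipped@loadings <- -flipped@loadings
  expect_equal(correlateLoadings(pca, flipped, 1:2, 50)$r, 1.0,
               tolerance = 1e-12)

  # independent analyses: small |r|; t-based p close to a permutation p
  pcaB <- runPCA(matrix(rnorm(8 * 100), 8, 100,
                        dimnames = dimnames(M)))
  cl <- correlateLoadings(pca, pcaB, 1:2, 50)
  expect_lt(abs(cl$r), 0.6)
  LA <- rowMeans(pca@loadings[cl$genes, 1:2])
  LB0 <- pcaB@loadings[cl$genes, 1:2]
  for (j in 1:2) if (cor(pca@loadings[cl$genes, j], LB0[, j]) < 0)
    LB0[, j] <- -LB0[, j]
  LB <- rowMeans(LB0)
  permP <- mean(replicate(2000, {
    abs(cor(LA, sample(LB))) >= abs(cl$r)
  }))
  expect_lt(abs(cl$p_value - permP), 0.05)
})

test_that("region exclusion drops overlapping genes only", {
  genes <- data.frame(gene_id = c("in", "edge", "out"),
                      chrom = c("6", "6", "2"),
                      start_bp = c(26e6, 34.9e6, 26e6),
                      end_bp = c(27e6, 35.5e6, 27e6))
  kept <- excludeRegion(genes)
  expect_equal(kept$gene_id, "out")
})
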