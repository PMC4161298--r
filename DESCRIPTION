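Package: disPCA
Title: Shared Pathogenetics Across GWAS Datasets via Gene-Level PCA
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterizes shared genetic architecture across genome-wide
    association study (GWAS) datasets from summary statistics alone. SNP
    association p-values are combined into gene-level statistics (minimum p,
    truncated product, truncated tail strength) and calibrated against an
    empirical null built from random groups of consecutive SNPs. The resulting
    dataset-by-gene matrix of -log10 gene p-values is optionally residualized
    on study-level confounders (genotyping array, association method, log10
    sample size), decomposed by centered unscaled singular value
    decomposition, and datasets are clustered hierarchically in principal
    component space. Includes a Fisher's-method test for non-random
    distribution of one disease's significant genes in another, a pleiotropy
    simulation framework, and export of pre-ranked gene lists for enrichment
    tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: GenomeWideAssociation, PrincipalComponent, Clustering, SNP
Config/testthat/edition: 3
RoxygenNote: 7.3.3
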