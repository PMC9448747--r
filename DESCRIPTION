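Package: svscape
Title: Population-Differentiated Structural Variants Linked to Lung Cell Types
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.com",
    role = c("aut", "cre"))
Description: An integrative analysis toolkit linking population-differentiated
    structural variants (SVs) to cell types. Implements SV call-set merging and
    filtering with a multi-sample genotype matrix, per-SV Weir-Cockerham FST with
    top-quantile candidate selection, strand-aware genomic-region classification
    with frameshift calling for deletions, bulk differential expression by
    median-of-ratios normalization plus a Welch t-test decision rule, a
    lightweight cross-species single-cell clustering pipeline (log-normalization,
    PCA, shared-nearest-neighbor Louvain, Wilcoxon markers, cluster-profile
    Pearson correlation with novel-cluster flagging), and per-cluster gene-list
    enrichment statistics (Fisher's exact, chi-square, one-vs-rest ratio tests).
    Ships a synthetic-data generator that emulates every input with known truth,
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
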