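Package: discoex
Title: Consensus Coexpression Networks and Their Disruption in Subfertile Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting disrupted testis
    gene-coexpression networks in subfertile hybrid house mice, and for any
    two-cohort consensus network study of the same design. Covers raw
    intensity preprocessing (background correction, negative-control
    expression filtering, quantile normalization, empirical-Bayes batch
    adjustment, PCA), fertility and expression-class assignment, signed
    consensus weighted network construction (soft-thresholded adjacency,
    topological overlap, dynamic tree cut, eigengenes, module-trait
    correlation), permutation-based module preservation statistics
    (Z_summary, median rank, seven-statistic significance tests),
    differential correlation of module genes, hub-gene identification, and
    gene-set / genomic-interval enrichment. Includes a synthetic-data
    generator with planted modules, batch effects, phenotypes and targeted
    module disruptions so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    GenomicRanges,
    IRanges,
    SummarizedExperiment,
    limma,
    sva,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'config.R'
    'io.R'
    'simulate.R'
    'preprocess.R'
    'classify.R'
    'network.R'
    'preservation.R'
    'diffcor.R'
    'enrichment.R'
    'pipeline.R'
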