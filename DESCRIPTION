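Package: gwasFunnel
Title: Candidate-Gene Identification Funnel Combining GWAS and
    Co-Expression Network Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for narrowing a genome-wide marker panel
    down to a handful of key candidate genes for a replicated quantitative
    trait. The funnel computes per-sample BLUP trait values from replicated
    measurements, runs single-locus (GLM/MLM with kinship and principal
    component covariates) and multi-locus (two-stage empirical-Bayes,
    LOD-scored) genome-wide association scans, intersects significant loci
    across models into quantitative trait nucleotides (QTNs), extracts
    genes within flanking windows, performs weighted gene co-expression
    network analysis (soft thresholding, topological overlap, module
    eigengenes, hub genes), tests per-SNP genotype-group trait effects with
    ORF-based mutation-consequence classification, builds thresholded
    correlation networks against a key-enzyme gene panel, and classifies
    genetic effects into a seven-class dominance taxonomy. A synthetic-data
    generator with a ground-truth ledger emulates the core-collection data
    structure so every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    lme4,
    igraph,
    jsonlite,
    tools,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GenomeWideAssociation, GeneExpression, Network, SNP,
    QualityControl, Software
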