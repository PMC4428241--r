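Package: panstrain
Title: Strain-Level Gene Content Variation from Metagenomic Coverage Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying strain-level gene content variation of
    bacterial species across individuals from per-gene metagenomic read
    coverage. Implements coverage-based gene presence calling with a
    replicate-calibrated gene-length coverage cutoff, sample and cohort
    filtering (breadth, marker-gene and depth criteria), core/accessory/
    unobserved gene classification, rarefaction-based extrapolation of the
    accessory-gene percentage with exponential, power-law, negative
    exponential and spline models, detection and classification of gene
    deletion blocks along reference contigs, symmetric-difference gene
    content distances between individuals and replicates, rank-sum
    comparison of distance distributions, Fisher-test functional-category
    enrichment, and a synthetic strain-community generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Coverage, Software
RoxygenNote: 7.3.3
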