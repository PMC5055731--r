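Package: epicqc
Title: Quality Screens and Cross-Platform Evaluation for Infinium-Style
    Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Array QC", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate Infinium-style DNA methylation BeadChip
    designs against a reference genome, population variant catalogs,
    regulatory annotation and whole-genome bisulphite sequencing (WGBS).
    Implements in-silico bisulphite-converted genome construction and a
    seed-and-extend homology scan for cross-reactive probe detection,
    classification of genetic variants overlapping probe footprints
    (target CpG, single-base-extension site, probe body), regulatory
    coverage accounting with >=1/>=2/>=3 probe stratification,
    beta-value and M-value computation with empirical detection
    p-values, differential methylation calling with empirical-Bayes
    variance moderation, and region-level array-versus-WGBS concordance
    at distal DNase hypersensitive sites, including typing of
    disagreement loci. A synthetic-data module generates every input
    with known ground truth so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
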