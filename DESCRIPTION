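Package: cnascanner
Title: High-Resolution Allele-Specific Copy Number Calling for
    Single-Cell Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects somatic copy number alterations (CNAs) in single-cell
    whole-genome sequencing data at high resolution by combining read-depth
    ratio (RDR), phased B-allele frequency (BAF) and haplotype information.
    Provides an allelic-dropout-aware minimum bin-size selector based on a
    two-state hidden Markov model, GC-bias normalisation of binned read
    counts, joint multi-cell segmentation under a simplified Bayesian
    information criterion, per-segment loss-of-heterozygosity testing and
    BAF refinement, and maximum-likelihood inference of the cell-specific
    ploidy scale factor and integer allele-specific copy numbers. A
    synthetic-diploid simulator (binned allele-specific depth with
    amplification noise, allelic dropout and phase-switch errors) and an
    evaluation harness (precision/sensitivity, FDR-by-size, clonality)
    make the whole pipeline testable without external data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    mclust,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
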