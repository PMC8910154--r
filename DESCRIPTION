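Package: somapiR
Title: Somatic piRNA Identification, Characterization and Classification
    from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for identifying and characterizing
    PIWI-interacting RNAs (piRNAs) in somatic small RNA sequencing data.
    Size-filters and aligns reads with a built-in one-mismatch seed aligner,
    excludes reads overlapping other small non-coding RNA loci, annotates the
    remainder against piRNA loci with fractional multi-mapper (1/x) counting,
    and computes presence calls, chromosome RPKM profiles, genomic-context
    (transposon, transcript, pseudogene) ratios, biogenesis signatures
    (length/first-base distributions, 5'U and 10A biases, ping-pong 10-nt
    5'-overlap z-score), Wilcoxon differential expression, hypergeometric
    gene-set enrichment, and a from-scratch sparse PLS-DA disease classifier
    with leave-one-out cross-validation and VIP feature ranking. Ships a
    synthetic-data generator that emulates multi-group small-RNA cohorts so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    pROC,
    rlang,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
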