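Package: pirnaimmunity
Title: Strain-Specific piRNA Production and Transposon Immunity Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for studying how natural variation in
    piRNA production shapes immunity to transposable elements (TEs) in
    Drosophila strains. Covers small-RNA read preprocessing, mapping to
    canonical TE sequences (up to 3 mismatches) and to the genome (exact),
    piRNA-cluster assignment of single-mapped reads, size and first-
    nucleotide (1U) profiling, ping-pong 5'-overlap signatures with
    z-scores, RPM/RPKM/TPM normalization, TE copy-number normalization
    from DNA-seq coverage, maternal-deposition ratios between ovary and
    early-embryo libraries, differential piRNA abundance with
    pseudo-replicates, reactivity-piRNA correlation with exact permutation
    tests, and qPCR/ChIP calculators. Includes a synthetic-data generator
    that emulates strain-specific primary piRNA production so every stage
    can be verified without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
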