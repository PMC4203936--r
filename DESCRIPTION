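Package: riboTE
Title: Translation Efficiency Analysis and 5'UTR Structure Signatures
    for Ribosome Profiling
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies ribosome-footprint and mRNA-seq libraries into
    per-gene RPKM values with P-site and read-midpoint positional
    assignment, computes translation-efficiency (TE) changes between a
    control and a drug-treated condition with z-score classification of
    sensitive and resistant genes, and characterizes 5'UTRs with a
    parameter-table-driven nearest-neighbor folding engine (minimum free
    energy and McCaskill partition function), sliding-window free-energy
    and GC profiles, 5'TOP motif and (CGG)4 repeat detection, and a
    structure-disrupting mutation designer.  A deterministic synthetic-data
    generator emulates a two-condition ribosome-profiling experiment so
    the whole pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
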