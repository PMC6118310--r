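Package: tandemscan
Title: Detection and Evolutionary Characterization of Tandem Duplicate Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies tandem duplicate gene clusters and interleaved duplicate
    cassettes from genome annotation and coding sequence, using gap-down-weighted
    pairwise protein similarity between proximal genes. Characterizes the genomic
    context of duplicates (window-based feature densities, a general linear model
    of duplicate density, transposable-element containment and capture, GC
    content), estimates duplication ages by molecular-clock calibration against an
    outgroup, compares duplicate content across two genotypes, and classifies
    evolutionary-rate outcomes from externally computed likelihood tables. A
    seeded synthetic-genome generator plants duplicates of controlled divergence
    and age so the whole pipeline is testable without external assemblies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
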