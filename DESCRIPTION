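Package: starscreen
Title: Detecting Horizontal Transfer of Giant Fungal Transposons from
    Genome Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers recent horizontal transfer of giant fungal transposons
    (Starships) between genome pairs by the best-hit identity screen: every
    annotated gene of one strain is searched against the assembly of another,
    the single best alignment per gene is kept, and genes whose identity and
    alignment length vastly exceed the genome-wide vertical-descent background
    (about 72 percent identity between distant congeners) are flagged as
    transfer candidates.  Candidate genes are clustered into cargo
    neighborhoods, element presence is called per strain from read-coverage
    breadth over an element reference, and haploid-cross segregation of
    element-linked phenotypes is modelled with exact tests.  A calibrated
    synthetic genome-pair generator reproduces the statistical structure of
    real inter-species comparisons so the whole pipeline is testable without
    external data, and a dinucleotide-index profiler flags repeat-induced
    point (RIP) hypermutation in element copies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
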