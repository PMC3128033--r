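Package: covmine
Title: Mining Irreducible Regions of Expression from RNA-Seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exploratory analysis of RNA sequencing data at nucleotide
    resolution. Builds per-base coverage from minimally-attributed aligned
    reads (chromosome, start, end, strand), mines maximal irreducible regions
    of expression above a coverage threshold with an adaptation of the
    Aumann-Lindell quantitative association rule algorithm, computes
    nucleotide-level fold change and splicing index, scans genic, extended
    and intergenic regions for novel transcription, and exports count tables
    for downstream count-based differential-expression tools. Includes a
    seeded read simulator with negative-binomial exon expression, uniform
    background noise and amplification-artifact spikes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    withr,
    IRanges,
    GenomicRanges,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    edgeR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
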