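Package: cistrans
Title: Cis/Trans Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("Diana", "Rueda", email = "drueda@example.org", role = c("aut", "cre"))
Description: Infers gene co-expression networks from two-phenotype log2
    expression matrices using binned mutual information with permutation
    significance, detects weighted communities, and quantifies chromosomal
    (cis/trans) and differential-expression assortativity. Includes
    hypergeometric overrepresentation analysis of GMT term sets and
    copy-number peaks within communities, annotation of transcription-factor
    regulon edges and CTCF peak classes from BED interval tracks, and a
    seeded synthetic-data generator that plants cis/trans block covariance
    structure so the full pipeline is testable without controlled-access
    tumor data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    igraph,
    Rcpp,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
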