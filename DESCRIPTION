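Package: itrtools
Title: Transposon ITR Remnant Detection and Regulatory Integration
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects decayed inverted terminal repeats (ITRs) of DNA
    transposons such as Hsmar1 in genome sequence, classifies remnants
    (solo ITRs, Made1-like miniature elements, paired remnants), relates
    ChIP binding peaks and differential-expression calls to ITR positions,
    quantifies over-representation with hypergeometric tail tests, and
    computes binned coverage metaprofiles around reference points. Ships a
    fully specified synthetic-data generator with ground-truth manifests so
    every stage is testable end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
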