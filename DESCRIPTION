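Package: markdiff
Title: Differential Histone-Mark Analysis and Expression Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for two-group differential analysis of a
    broad repressive histone mark (H3K9me3 ChIP-seq) and its integration with
    mRNA-seq. Implements trimmed-mean-of-M-values (TMM) normalization, a
    negative-binomial conditional exact test, a permutation-derived
    fold-change cutoff, sliding-window broad-domain calling with cross-sample
    consensus regions, promoter and gene-body differential marking, metagene
    occupancy profiles stratified by expression, and the identification of
    genes whose histone-mark and expression changes diverge. Ships a
    negative-binomial synthetic-data generator with planted ground truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    yaml,
    ape,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    Rsamtools,
    optparse,
    knitr
Config/testthat/edition: 3
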