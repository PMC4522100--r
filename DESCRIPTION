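Package: bisamp
Title: Targeted Bisulfite Amplicon Sequencing: Panel Design, Read
    Simulation, Methylation Calling and Group Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for targeted bisulfite amplicon sequencing assays in
    which libraries are built by two rounds of PCR (adapter-overhang target
    enrichment followed by index barcoding). Models amplicon panels with
    in-silico bisulfite conversion and CpG enumeration, predicts final
    library fragment lengths, simulates bisulfite-converted paired-end reads
    with ground truth, aligns reads to converted amplicon references in a
    reduced (three-letter) alphabet, quantifies per-CpG methylation with a
    first-read-precedence overlap rule, reports library balance, and tests
    two-group differential methylation per CpG and per region.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
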