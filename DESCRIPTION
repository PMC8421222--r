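Package: primeredit
Title: Sequencing-Based Measurement of Primer Editing by Proofreading
    Polymerases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for measuring primer editing, the correction of
    template:primer mismatches by the 3'->5' proofreading exonuclease of
    high-fidelity DNA polymerases, from amplicon sequencing data.  Designs
    a pool of synthetic standard constructs carrying every single-base
    substitution in the 3'-terminal window of a forward primer binding
    site, each tagged with a PCR-free quantification barcode; simulates
    paired-end amplicon reads from the pool under an explicit generative
    model of per-position editing efficiency and mismatch amplification
    penalty; quantifies pool composition from barcode reads with a
    Hamming-distance tolerance; and computes per-position base
    composition, the observed/expected edits metric, and fold-of-expected
    amplification penalties for variant primers.
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
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
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
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
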