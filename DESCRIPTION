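Package: pegbe
Title: Prime Editing pegRNA and Base Editor Guide RNA Design
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and score prime-editing pegRNAs (PE2), select PE3 and
    PE3b nicking guides, and design adenine/cytosine base-editor guide RNAs
    across a registry of Cas9 PAM variants with editing-window and bystander
    logic. Works from raw target sequences, genomic coordinates against a
    user-supplied indexed FASTA, batch variant tables, or ClinVar-style
    variant summaries, and exports Golden Gate-ready cloning oligos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
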