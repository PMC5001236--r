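Package: flowcallr
Title: Bayesian and Reference-Guided Homopolymer Length Calling for
    Semiconductor Sequencing Flow Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls homopolymer lengths from semiconductor (Ion
    Torrent/Proton style) flow voltage signals. Fits class-conditional
    Gaussian voltage models stratified by nucleotide, read-position zone
    and homopolymer length, computes Bayesian posterior length
    probabilities, and combines them with a reference-genome mismatch
    penalty in a weighted integrated score whose weight is chosen by
    cross-validation. Includes a nearest-mean baseline caller, a
    deterministic flow-signal simulator with variant injection for
    generating labelled benchmark data, an evaluation harness producing
    per-nucleotide, per-zone error tables, and readers/writers for the
    flowgram TSV, priors JSON and FASTA formats used throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
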