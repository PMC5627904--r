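Package: nanobar
Type: Package
Title: Reference-Guided Consensus Calling for Nanopore DNA Barcoding
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for species identification from noisy long-read barcode
    amplicons. Simulates 2D nanopore-like reads with per-base mismatch,
    insertion and deletion rates plus homopolymer length errors; builds a de
    novo draft consensus by partial-order alignment; retrieves the best
    matching record from a local barcode reference database by k-mer
    prefiltered semi-global alignment; realigns reads to that reference and
    calls a per-position nucleotide-frequency (majority vote) consensus; and
    reports error decomposition, homopolymer coverage dips and per-channel
    run-count normalisations.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
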