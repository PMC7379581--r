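Package: metabarprime
Title: Design and In Silico Evaluation of Metabarcoding Primers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing degenerate PCR primers from multiple
    sequence alignments and for evaluating metabarcoding markers in
    silico against taxonomy-annotated mitochondrial reference databases.
    Emulates PCR amplification of IUPAC-degenerate primer pairs
    (mismatch budgets, 3' anchoring, inosine pairing modes, circular
    templates, amplicon length windows), clusters predicted amplicons
    with greedy centroid clustering across identity thresholds, and
    scores markers with taxonomic coverage and resolution indices
    (B_C, B_S, B_E, B_E', ETR), including two-marker combination
    strategies and barcoding-gap detection. Ships a synthetic
    reference-database simulator with planted primer sites and
    controlled divergence structure for validation with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
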