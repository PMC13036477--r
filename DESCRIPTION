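Package: fieldamp
Title: Field-Deployable Amplicon Metabarcoding with De Novo Reference
    Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-step metabarcoding workflow for biodiversity monitoring
    with noisy long reads: single-specimen consensus barcoding feeds locally
    generated reference sequences into a MIDORI2-style reference database,
    which then drives best-hit taxonomic assignment of eDNA amplicon reads at
    dual percent-identity thresholds. Includes dual-index demultiplexing by
    bounded edit distance, quality and length filtering, exact dereplication,
    noise-floor and negative-control filtering, detection and elevational
    summaries, risk-ratio accuracy evaluation against a locality checklist,
    degenerate primer elongation from curated alignments, and a Nanopore-like
    read simulator so the whole pipeline runs without downloads.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
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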