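Package: plastidflow
Title: Plastome Rearrangements, Strand-Specific Transcription and RNA Editing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline linking plastid genome rearrangements to
    gene-expression divergence. Provides strand-specific coverage profiling
    from plain-text SAM alignments, TPM quantification and ortholog
    expression correlation, synteny-block construction with breakpoint and
    double-cut-and-join (DCJ) rearrangement distances on circular signed
    gene orders, strand-aware C-to-U RNA-editing detection with binomial
    filtering and silent/non-silent/antisense classification, patristic
    distances, and correlation-of-correlations association statistics. A
    synthetic-data module simulates operon-structured circular plastomes,
    segmental inversions, polycistronic transcription with read-through,
    pervasive antisense background, injected C-to-U edits, and
    dUTP-protocol strand-specific read pairs with a ground-truth manifest,
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
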