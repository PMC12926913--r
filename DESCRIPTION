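Package: polcensus
Title: Annotation of Bacterial DNA Polymerase Complements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and annotates DNA polymerases of the A, B, C, X and Y
    families in bacterial proteomes. Provides a packaged ontology of polymerase
    groups, domains and motifs; a position-specific scoring profile scanner for
    domain detection; active-site and interaction-motif calling (PHP, DEDDh,
    DEDDy, FEN, beta-clamp and RecA-NT motifs); per-genome integration into
    replication-system types, proofreader censuses and 5'-3' exonuclease
    complementation status; decision-table typing of multimeric error-prone
    (mutasome) polymerase complexes; presence-absence enrichment statistics with
    Fisher's exact test; and a synthetic-proteome generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    igraph
Suggests:
    rtracklayer,
    withr,
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
LinkingTo: Rcpp
VignetteBuilder: knitr
Config/testthat/edition: 3
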