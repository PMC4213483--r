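Package: coexnet
Title: Signed Co-Expression Networks, Module Preservation, Trajectory
    Classification and Promoter Motif Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end workbench for weighted gene co-expression
    network analysis of microarray-style expression studies of neural
    differentiation and depolarization. Builds signed adjacency and
    topological-overlap networks, detects and merges co-expression
    modules, summarizes them by eigengenes and kME, tests module-trait
    association with Benjamini-Hochberg correction, assesses module
    preservation between data sets by permutation Zsummary statistics,
    classifies genes into differentiation-trajectory categories from
    paired and factorial moderated-t tests, performs Fisher and
    permutation gene-set over-representation, and scores promoter
    sequences for transcription-factor binding-site enrichment against
    empirical backgrounds. A synthetic-data generator with known ground
    truth emulates the case/control progenitor-neuron-depolarization
    study design for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
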