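Package: routescape
Title: Invasion Routes and Cell States in Glioblastoma Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reimplements, as a tested analysis workflow, the computational
    chain linking glioblastoma invasion routes to transcriptional cell
    states: multiplex-immunofluorescence compartment segmentation and
    per-compartment protein scoring, single-cell quality control, 4-state
    ("butterfly") embedding and state-route association, regulatory-landscape
    meta-analysis with metamodules and regulator selectivity, Kalman-filter
    time-lapse cell tracking with vessel association, and survival
    statistics (Kaplan-Meier/logrank, cluster-robust Cox). A seeded
    synthetic-data module emulates every input with planted ground truth so
    each stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    survival,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
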