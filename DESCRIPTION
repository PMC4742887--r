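Package: myoscreen
Title: High-Content siRNA Screen Analysis for Kinase Repressors of
    Myogenic Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing kinome-wide high-content RNA-interference
    screens that read out Myogenin induction in proliferating myoblasts.
    Provides plate-resolved data structures and validated CSV I/O for
    per-site nuclei counts, a seeded negative-binomial/beta-binomial plate
    simulator with planted-hit ground truth, robust Z-score and MAD plate
    statistics with Z-factor assay-window quality control, the
    two-criterion (Myogenin t-test plus cell-number MAD) replicate-aware
    hit-calling procedure with a CDK4/6-inhibitor sensitizer arm,
    cross-arm hit-set comparison, protein-interaction-network
    classification of hits as direct or semi-direct regulators of
    myogenic regulatory factors with Cytoscape SIF export, and binomial
    pathway enrichment against the screened library background with
    Benjamini-Hochberg false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
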