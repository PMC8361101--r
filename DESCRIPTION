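Package: dynppi
Title: Dynamic Protein-Interaction Network Analysis of Time-Course
    Phosphoproteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers chronologically dynamic pathological protein-protein
    interaction (PPI) networks from multi-model, multi-timepoint
    phosphoproteome quantification data. Differentially phosphorylated
    sites (Welch test, Benjamini-Hochberg adjustment) seed per-model,
    per-timepoint PPI subnetworks; hub proteins are ranked by betweenness
    centrality and edges are selected by cosine similarity of
    three-timepoint disease/control ratio trajectories. Per-model evidence
    is aggregated into disease-group core networks and their common core,
    with validation machinery: a bootstrap commonness null with
    truncated-normal standardization, hold-out and cross-validation
    precision, correlation-error MAE/RMSE, and physical-interaction
    enrichment. Includes a synthetic-data generator with a planted core
    module so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
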