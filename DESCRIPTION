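Package: mcnet
Title: Vertex-Level Myelin Covariance Networks: Gradients, Strength, and
    Graphlet Landscape
Version: 0.1.0
Authors@R:
    person("mcnet", "developers", email = "mcnet@example.org",
           role = c("aut", "cre"))
Description: Builds vertex-level myelin covariance networks (MCNs) from
    subject-by-vertex T1w/T2w myelin-proxy maps: residualizes maps against
    age, age-squared, gender and age-by-gender confounds, computes the
    vertex-wise Pearson covariance network and its signed connectivity
    strength maps, approximates principal gradients with a landmark-based
    decomposition, profiles results over cytoarchitectonic classes, decodes
    against term-map banks, correlates with multimodal cortical features
    under Bonferroni/Holm correction, and characterizes higher-order
    topology via an exact and sampled census of the 30 connected 2-5 node
    graphlets in Przulj order. Includes a synthetic-cohort generator with
    planted low-rank structure so the whole pipeline is testable without
    restricted neuroimaging data, plus a config-driven pipeline and CLI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
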