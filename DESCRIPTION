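Package: netreg
Title: Upstream Regulator Inference from Signed Directed Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative network topology analysis for omics gene sets on
    signed, directed molecular-interaction networks. Implements paired
    differential-expression filtering, hypergeometric overconnectivity
    testing of direct neighbourhoods, a "hidden nodes" statistic based on
    transcription-activation shortest paths with sign-parity constraints,
    weighted Spearman-footrule rank aggregation by a genetic algorithm,
    receptor- and transcription-factor-centred subnetwork construction with
    enrichment scoring, and an end-to-end pipeline that classifies candidate
    upstream receptors by topological significance and overexpression of the
    receptor or its ligands. Includes a synthetic-data generator that plants
    ligand-receptor-kinase-TF-target cascades with known ground truth for
    benchmarking every stage.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    optparse,
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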