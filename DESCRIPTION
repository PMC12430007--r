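Package: macsig
Title: Multi-Omics Signaling Analysis of Macrophage Polarization States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential (phospho-)proteomics with PTM-level adjustment against
    protein abundance, left-censored downshifted-normal imputation, kinase-activity
    footprint inference from curated and predicted kinase-substrate relations,
    cross-dataset consensus of bulk RNA-seq differential expression and transcript
    usage, integrative protein-interaction networks with current-flow betweenness
    centrality and modularity-based module decomposition, hypergeometric
    over-representation analysis with redundancy pruning, and signature-based
    classification of single-cell macrophages into M1-like and M2-like states.
    Includes a seeded synthetic-data generator emulating the statistical structure
    of each input layer, with planted ground truth for recovery testing, and a
    pipeline orchestrator driven by a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
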