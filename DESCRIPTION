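Package: strufun
Title: Protein Function Prediction from Residue Contact Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology annotations for proteins from predicted
    3D structures. Residue contact graphs are built from alpha-carbon
    coordinates, residues are embedded by biased (node2vec-style) random
    walks trained with skip-gram negative sampling, whole-graph structural
    features are extracted by a two-layer graph-convolution network with
    self-attention top-rank pooling, fused with a per-protein sequence
    embedding, and fed to a hierarchy-aware multi-label classifier.
    Includes CAFA-style protein-centric evaluation (Fmax, AUC, AUPR),
    true-path-rule label propagation over the GO DAG, and a seeded
    synthetic-data generator so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    seqinr,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
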