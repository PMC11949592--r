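Package: amynet
Title: Multimodal MRI Deep Learning for Amyloid Status Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: A multimodal deep-learning framework that classifies amyloid-beta
    status (CSF Abeta42 below 980 pg/ml) from three MRI-derived views of the
    brain: gray-matter probability volumes analysed by a 3D convolutional
    network, 53-node functional network connectivity (FNC) graphs analysed by a
    graph convolutional network, and 84-node structural connectome graphs
    analysed by a Chebyshev spectral graph network. Branch latents (100
    features each) are concatenated into a 300-feature vector and classified by
    a multilayer perceptron trained with weighted cross entropy under
    stratified cross-validation. Post hoc explainability uses guided
    backpropagation to derive voxel- and node-level attribution maps, regional
    percentage contributions and top-10 rankings, followed by Mann-Whitney
    tests with Benjamini-Hochberg correction on region-level input features
    (regional gray-matter means, FNC node strength, structural betweenness
    centrality). A synthetic-cohort generator emulates atlas-structured
    volumes, correlation-valued FNC matrices and streamline-count matrices
    with group-dependent effects so the full pipeline is testable without
    access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
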