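Package: cellgraphnet
Title: Cell Spatial Graph Convolutional Networks for Pathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds directed k-nearest-neighbour cell spatial graphs from
    tables of segmented nuclei (centroids, cell types, orientation and ten
    morphology features), and trains small edge-conditioned graph
    convolutional networks on them.  Each convolution is modulated by the
    categorical edge type (ordered pair of cell types) and by two continuous
    spatial interaction features, nuclear parallelism and nuclear closeness,
    via feature-wise linear modulation.  Includes task heads for histology
    classification, risk stratification and treatment-response prediction,
    gradient-based attribution of predictions to individual node and edge
    features, patch-to-slide and patch-to-patient aggregation, and a
    synthetic tissue simulator (hard-core point process with tunable
    cell-type mixtures, ellipse morphology and orientation coherence) so the
    whole pipeline can be exercised without access to pathology images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
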