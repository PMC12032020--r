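Package: gradmosaic
Title: Multimodal Cortical Gradient Profiles and Areal Dissimilarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds vertex-wise microstructural profile covariance (MPC),
    structural (SC) and functional (FC) connectomes, derives diffusion-map
    gradients from normalized-angle affinities, aggregates them into
    area-wise multimodal gradient profiles, and quantifies local versus
    global cortical organization through inter-/intra-areal cosine
    dissimilarity, cross-task functional diversity, hierarchical clustering
    of areal similarity, and spherical spin-permutation inference. Includes
    a synthetic cortical dataset generator (icosphere meshes, probabilistic
    Voronoi parcellations, planted smooth gradients, multimodal data with
    controllable signal-to-noise) so the full pipeline is testable without
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
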