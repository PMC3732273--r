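Package: atlasmanifold
Title: Manifold-Guided Atlas Selection and STAPLE Fusion for Multi-Atlas Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Atlas selection for multi-atlas segmentation of brain structures
    using non-linear manifold learning on a deformation-field distance.
    Implements a root-mean-square displacement-field metric mediated through a
    common average atlas, Isomap, Locally Linear Embedding and Laplacian
    Eigenmaps embeddings of an atlas library, Nystrom out-of-sample extension
    of unseen targets, k-nearest-atlas selection on the manifold, STAPLE label
    fusion with a mean-field Markov random field restricted to non-consensus
    voxels, leave-one-out grid search over technique and parameters, and a
    synthetic phantom generator with known low-dimensional latent structure
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
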