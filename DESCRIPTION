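Package: elastroot
Title: Elastic Shape Statistics and Classification of Tap-Root-Like 3D Shapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric statistical shape analysis for tap-root-like 3D objects
    such as sugar beet storage roots. Closed triangle meshes are converted to
    characteristic functions on a regular grid via signed distances (Eikonal
    equation, fast marching) with a variational sign regularization, and
    volume-normalized. Ensembles are summarized by an elastic shape average that
    minimizes a hyperelastic matching energy, principal modes of shape variation
    are computed by a Gram-matrix PCA of boundary-stress-induced displacements
    under the Hessian-induced elastic metric, and unseen shapes are assigned to
    groups (cultivars) with an extended Mahalanobis distance. A seeded parametric
    generator of labeled synthetic root ensembles and a five-trait Euclidean PCA
    baseline are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
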