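Package: cranioform
Title: Homologous Cranial Surface Models, Shape-Space PCA, and Allometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dense-correspondence (homologous) cranial surface
    modelling. A bilaterally symmetric template mesh carrying 56 named
    craniometric landmarks is registered to each specimen scan by
    landmark-guided rigid alignment followed by stiffness-regularised
    non-rigid deformation, Loop subdivision, and a final fine fit, so that
    every specimen is represented by a mesh with identical topology and
    vertices in anatomical correspondence. Downstream analyses operate on
    the flattened vertex coordinates expressed in a Frankfurt-based
    head-oriented frame: principal component analysis of the coordinate
    table (dual/Gram form), per-vertex loading colour maps, virtual shapes
    along component axes, one-vs-rest ROC/AUC group discrimination with
    Hanley-McNeil chi-square significance, and allometric regression of
    component scores on centroid size via the log-log power law Y = a*X^b.
    A synthetic-anatomy generator produces cranium-like surfaces with known
    shape modes, group structure and analytically placed landmarks for
    validation and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    ggplot2,
    rlang,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
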