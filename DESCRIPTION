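Package: craniomorph
Title: Statistical Shape Modeling and Classification of Craniosynostosis
    from 3D Head Surface Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A radiation-free analysis pipeline for craniosynostosis built on
    photogrammetric 3D head surface scans. A symmetric template mesh is morphed
    onto each target scan with optimal-step nonrigid ICP (one affine transform
    per vertex) after a landmark-based similarity alignment, establishing dense
    correspondence. A point distribution model is then built with weighted PCA
    via the Gram-matrix (dual) route, using a barycentric-cell mass matrix so
    surface regions contribute by area rather than vertex density. Head shapes
    are classified into control, coronal, sagittal and metopic classes from the
    cranium-only model's shape coefficients with mirror-aware stratified
    cross-validation. Includes model quality metrics (compactness,
    generalization, specificity), shape editing by attribute regression
    (pathology removal), fixed-cranium flexibility modes via a constrained
    generalized eigenvalue problem, and a seeded generator of synthetic
    class-specific head scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Matrix,
    MASS,
    e1071,
    rpart,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
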