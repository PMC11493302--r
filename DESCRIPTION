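Package: auriclass
Title: Morphological Ear Classification from 3D Homologous Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds morphological classification criterion images (CCIs) for the
    human external ear from triangle meshes in dense vertex-wise correspondence.
    Provides mesh and landmark I/O (STL/PLY/OBJ with JSON sidecars), a synthetic
    ear-cohort generator with known latent deformation modes, landmark-guided
    template fitting (similarity Procrustes, thin-plate-spline warp, surface
    projection), generalized Procrustes alignment, coordinate principal component
    analysis with eigenvalue/contribution-ratio tables, scree- and
    distance-between-vertices (DBV)-based component selection, two-stage PCA
    synthesis of composite and classification criterion images, and
    nearest-prototype classification of ear meshes by minimum mean DBV with
    threshold and multi-match logic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
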