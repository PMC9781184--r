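Package: ancftendon
Title: Achilles Subtendon Mechanics with ANCF Continuum Beam Elements
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Static finite-element analysis of the human Achilles tendon
    modelled as three pretwisted subtendon beams that slide against each
    other. Implements the three-node 3363 absolute nodal coordinate
    formulation (ANCF) continuum beam element with deformable cross-sections,
    Gauss-Green cubature over spline-bounded cross-section domains, a
    near-incompressible neo-Hookean material via a volumetric penalty,
    frictionless surface-to-surface penalty contact between beams, and a
    Newton load-stepping solver. Ships synthetic subtendon cross-section
    fixtures scaled to published areas, CSV/VTK/JSON result export and a
    small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
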