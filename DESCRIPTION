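Package: pappus
Title: Plane-Strain Mechanics of the Dandelion Pappus Hygroscopic Actuator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the apical plate of the dandelion diaspore as a
    two-dimensional, plane-strain, isotropic linearly elastic structure in
    which four tissue regions (floral podium, vasculature, side regions,
    cortex) shrink by different amounts on dehydration. Differential
    hygroscopic eigenstrain around a central cavity generates the pappus
    holding angle. The package builds the parametric section geometry,
    meshes it, solves the dehydration problem with a built-in finite
    element kernel, fits the intrinsic swelling factors to regional
    expansion targets, performs one-at-a-time sensitivity analysis with
    first-order correlation propagation, quantifies tissue deformation
    from paired dry/wet landmark sets via Delaunay triangulation, and
    extracts effective Young's moduli from AFM force curves with a
    Sneddon conical-indenter fit. Synthetic-data generators emulate
    landmark sets, force curves and correlated geometry samples so every
    stage can be exercised without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
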