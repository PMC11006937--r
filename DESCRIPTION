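Package: craniofem
Title: Comparative Cranial Finite-Element Analysis on Tetrahedral Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A linear-elastic finite-element pipeline for comparative cranial
    biomechanics on four-noded tetrahedral (tet4) meshes. Provides a
    constant-strain-tetrahedron solver with exact constraint elimination,
    readers and writers for a minimal Abaqus-INP dialect and legacy-ASCII VTK,
    scenario builders for surface-area-scaled palatal bending tests,
    muscle-driven bite simulations with constrained bite points, extrinsic
    head-pull/shake/twist load cases, and keratinous rhamphotheca material
    overlays, plus comparative summary statistics (top-5%-trimmed von Mises
    stress and volume-corrected total strain energy). Includes generators for
    synthetic validation geometry: structured cantilever beams with analytic
    beam-theory solutions and bilaterally symmetric toy-skull meshes carrying
    the landmark node sets (palate bite points, quadrate articular patches,
    occipital condyle, jaw-adductor origin patches) that the load protocols
    require.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
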