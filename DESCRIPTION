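Package: TMRefine
Title: Multi-Template Rigid-Body Refinement of Seven-Transmembrane Helix Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Refines the seven-transmembrane helix bundle of G-protein-coupled
    receptor backbone models by greedy rigid-body helix moves (translation,
    spin about the helix axis, tilt against the membrane normal) under a
    membrane-aware score that adds a bundle-packing penalty on the summed
    area of triangles fanned from the centroid of the helix-axis/midplane
    intersection points. Chain breaks introduced by rigid helix moves are
    re-closed by cyclic coordinate descent on loop backbone dihedrals.
    A parallelized-framework protocol runs eight region-assigned refinement
    pipelines over multiple template models, exchanges best-so-far helices
    between pipelines, and keeps an elite pool of low-energy conformations
    across iterations. Includes a synthetic ideal-bundle generator so the
    whole method is testable without external structure data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
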