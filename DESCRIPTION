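Package: cellosmo
Title: Single-Cell Osmotic, Mechanical, and Morphometric Biophysics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimation of single-cell membrane hydraulic permeability and
    osmotically active water fraction from osmotic-loading volume traces,
    using a mixture-theory Kedem-Katchalsky transport model for a
    nonpermeating solute. Includes forward simulation and nonlinear
    least-squares inversion of the volume-response model, Hertz
    spherical-indentation fitting of AFM force curves, image-based
    single-cell morphometry (segmentation, tracking, equivalent radius,
    circularity, size-normalized intensity, nuclear colocalization
    scoring, gating), seeded synthetic-data generators emulating the
    treatment groups of an osmotic-loading study of nucleus pulposus
    cells, and group-level statistics including cross-scale scaling
    regressions linking contractility, circularity, and permeability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    minpack.lm,
    EBImage,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Software, SingleCell
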