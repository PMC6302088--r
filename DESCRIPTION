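Package: guvkappa
Title: Electrodeformation Analysis of Giant Unilamellar Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the membrane bending stiffness of giant
    unilamellar vesicles (GUVs) from AC-field electrodeformation experiments.
    Provides exact prolate/oblate spheroid geometry (areas, volumes, pole and
    equator curvatures, fixed-volume deformation maps), a synthetic-data
    module that emulates phase-contrast microscopy of deforming vesicles with
    known ground truth, an ImageJ-style measurement chain (Otsu binarization,
    sub-pixel contour extraction, direct least-squares ellipse fitting,
    equivalent-diameter size distributions), and the bending-regime
    log-linear fit that converts the apparent-area response to a bending
    stiffness with propagated uncertainties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
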