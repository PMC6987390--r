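Package: stereoglia
Title: Design-Based Stereology of Microglial Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-probe design-based stereology for microglial morphometry:
    length density of cell processes by isotropic virtual planes and by
    cycloid test systems on total vertical projections, numerical density of
    cell bodies by the optical disector with section-thickness shrinkage
    correction, soma volume by the vertical rotator, and coefficients of
    error for systematic random samples. Includes a synthetic 3D
    microglia-tissue simulator with exact ground-truth morphometry
    (control and deafferented regimes), a confocal-like stack renderer with
    modality-dependent thin-process detection models, and an end-to-end
    experiment pipeline that recovers generating parameters and re-derives
    published summary percentages from packaged reference values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
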