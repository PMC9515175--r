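Package: colonymorph
Title: Morphometrics of Bacterial Macrocolonies Under One-Sided Antimicrobial Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the morphological and fluorescence-intensity response of
    bacterial macrocolony biofilms growing next to a one-sided antimicrobial
    source. Segments colony periphery and core from single-channel microscopy
    images (grayscale erosion, Otsu thresholding, border-following contour
    extraction), measures one-sided deformation by mirroring each half-contour
    about the axis through the seeding point and fitting ellipses, computes
    exposed/unexposed mean-intensity ratios and the leading-edge
    intensity-versus-distance regression, and compares treatment groups to
    control with two-sided Student's t-tests. Ships a seeded synthetic colony
    generator with ground truth so the whole pipeline is testable without real
    data, plus a command-line interface over all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
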