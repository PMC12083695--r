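Package: isoistroke
Title: Intrinsic Signal Optical Imaging and TTC Infarct Quantification for
    Rodent Stroke Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for widefield intrinsic signal optical imaging
    (ISOI) of the rodent barrel cortex in permanent middle cerebral artery
    occlusion (pMCAo) experiments. Builds trial-averaged fractional-change
    (dR/R) ratio images from raw frame stacks, quantifies whisker functional
    representations (areal extent and peak amplitude of the initial dip and
    overshoot phases) inside analyst-defined regions of interest, segments
    TTC-stained coronal slices to compute edema-corrected infarct volumes,
    and runs the associated statistical battery (mixed-design repeated
    measures ANOVA, corrected post hoc contrasts, infarct t-tests and
    slit-size regressions). A seedable synthetic-data generator emulates the
    five-group baseline versus 24-hour study design so every stage is
    testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
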