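Package: calciquant
Title: Quantification of Calcinosis Cutis Lesions in Finger Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify calcinosis cutis (CC) burden in 2D finger
    images. Healthy phalanges are segmented with a small trainable
    encoder-decoder network (or a classical intensity baseline), subtracted
    from the image, and residual calcified lesions are delineated by seeded
    region growing and reported as areas in square millimetres. The package
    also emulates the radiologists' ellipse-based area estimate from a
    lesion's maximal long axis and perpendicular short axis, and validates
    agreement between paired measurement methods with Spearman correlation,
    Lin's concordance correlation coefficient and Bland-Altman analysis.
    A built-in synthetic phantom generator with pixel-exact ground truth
    makes the whole pipeline testable end to end without any patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
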