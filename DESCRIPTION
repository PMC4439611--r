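Package: boneseg
Title: Humeral Head Segmentation in PD-Weighted Shoulder MR Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments the humeral head from 2D proton-density-weighted
    shoulder MR slices. The pipeline combines speckle-reducing anisotropic
    diffusion with a foreground-estimated noise scale, homomorphic bias-field
    correction, automatic circular-Hough localization of the humeral head,
    region-based level-set segmentation (active contours without edges and a
    signed-pressure-force model), Gaussian-mixture and fuzzy C-means
    clustering baselines, anatomical postprocessing that removes scapula and
    tendon attachments and fills bone-edema holes, and Sorensen-Dice
    evaluation. A seeded synthetic shoulder-phantom generator emulates
    normal, edematous, and Hill-Sachs humeral heads for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    e1071,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
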