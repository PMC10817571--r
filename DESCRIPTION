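Package: nervetrace
Title: Median Nerve Ultrasound Segmentation Phantoms, Encoder-Decoder
    Networks and Morphometric Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating automated median-nerve delineation in
    B-mode wrist ultrasound. Generates synthetic speckle phantoms with
    ground-truth nerve masks, trains compact U-Net and SegNet
    encoder-decoder segmentation networks (implemented natively with
    backpropagation and Adam), and quantifies results with per-image
    precision/recall/DICE/IoU, binary-mask morphometry (cross-sectional
    area, traced circumference, minimum-bounding-rectangle diameters) and
    method-comparison statistics (Spearman rank correlation with
    interpretation bands, Student's t-test, Bland-Altman limits of
    agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
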