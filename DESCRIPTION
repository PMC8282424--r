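Package: gliopipe
Title: Glioma Grading from H&E Histopathology with Molecular Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for computational glioma grading from
    hematoxylin-and-eosin (H&E) histopathology. Provides superpixel-based
    region-of-interest selection from whole-slide thumbnails,
    structure-preserving stain normalization by sparse non-negative stain
    separation, nuclei segmentation through a classical stain-threshold
    backend or a small trainable encoder-decoder network, tumor cellularity
    quantification with morphological dilation, and a cascaded two-stage
    classifier that fuses image patches with molecular markers (IDH, ATRX,
    1p/19q codeletion, MGMT methylation) and cellularity. A seed-controlled
    synthetic histology generator supplies ground-truth images, masks and
    molecular cohorts so the full pipeline can be exercised and validated
    without external slide archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    nnet,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
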