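Package: phenoscreen
Title: High-Content Screening Pipeline for Melanoma Phenotype-Switching Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-content imaging screens of melanoma
    phenotype switching: synthetic multi-channel plate/field generation with
    per-cell ground truth, top-hat nucleus detection and seeded cell-body
    segmentation, chord-based cell elongation morphometry, reporter-intensity
    classification, control-referenced per-well Z-scores and replicate-projection
    composite Z-scores, dose-response hit calling with dual-phenotype
    (proliferative and differentiated) calls, and small companion image
    quantifications (pigment-area fraction, tumour area and perimeter by
    automatic thresholding, relative melanin content from absorbance standard
    curves).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    jsonlite,
    rlang,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
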