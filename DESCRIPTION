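Package: qcdseg
Title: Quality-Control-Driven Ensemble Segmentation of Cardiac T1 Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble segmentation of the left-ventricular myocardium on
    quantitative cardiac T1 maps with built-in, per-image quality control.
    Several small fully-convolutional networks of graded depth each propose a
    myocardium mask; label voting over the single-model masks generates
    combined candidates; the matrix of inter-candidate Dice coefficients feeds
    per-model linear regressions that predict each candidate's Dice against the
    (absent) ground truth; and the candidate with the highest predicted Dice is
    selected on the fly. Includes a seeded synthetic short-axis phantom
    generator with graded image-quality tiers and artefacts, agreement-map
    visualization, selection variants (QCD-Lite, weighted average), and a full
    evaluation suite (Dice summaries, prediction error, good/poor
    classification, myocardial T1 estimation, Bland-Altman agreement).
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
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
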