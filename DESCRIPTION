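Package: fgsquant
Title: Quantitative Image Analysis for Fluorescence-Guided Surgery Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying fluorescence contrast between tumor and
    normal brain tissue when comparing contrast agents for fluorescence-guided
    surgery. Implements mask-based tumor-to-normal-ratio (TNR) quantification
    of multi-channel coronal section images (nuclear-dye segmentation,
    contralateral mirroring of the tumor ROI), a discriminative RGB-to-gray
    color projection for protoporphyrin IX blue-light images, weight-normalized
    homogenate TNR, ex-vivo fragment normalization and fold-difference, and the
    paired and unpaired nonparametric comparisons these designs call for. A
    synthetic phantom generator with known ground-truth contrast makes every
    stage of the pipeline testable without animal or patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    graphics,
    grDevices,
    stats,
    tiff,
    png,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
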