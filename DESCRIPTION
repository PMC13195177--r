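Package: ofvplan
Title: Objective-Function-Value Guided Automated VMAT Planning on Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained surrogate inverse-planning engine for studying
    objective-function-value (OFV) feedback control of VMAT optimization
    constraints.  Generates seeded two-dimensional thoracic phantoms with a
    coplanar arc beam geometry and a pencil-beam influence matrix, optimizes
    fluence against uniform-dose and maximum generalized equivalent uniform
    dose (MaxEUD) objectives, and adapts the per-organ MaxEUD limits between
    optimization loops with linear OFV-feedback update laws until saturation.
    Includes the sensitivity-score calibration of the feedback tuning points,
    target-coverage repair via the 95 percent isodose, dose-volume histograms,
    Paddick conformity index, homogeneity index, clinical-goal evaluation, and
    a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
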