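Package: octaclass
Title: Quantitative OCT-Angiography Features and Hierarchical Retinopathy Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts quantitative vascular and foveal features from en-face
    OCT-angiography (OCTA) images (blood vessel tortuosity, caliber, perimeter
    index, fractal-dimension vessel density, foveal avascular zone area and
    contour irregularity), selects optimal feature combinations per diagnostic
    task by univariate screening and stepwise backward elimination, and trains
    a hierarchical support-vector-machine classifier (control vs. disease,
    diabetic vs. sickle-cell retinopathy, severity staging) with full
    sensitivity/specificity/ROC/AUC reporting. Ships a synthetic vascular
    phantom generator with analytic ground truth so the whole pipeline is
    testable without clinical images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    EBImage,
    igraph,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    png,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
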