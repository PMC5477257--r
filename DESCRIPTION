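Package: GLCMSurv
Title: Masked GLCM Texture Features and Survival Association for CT Regions of Interest
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts grey-level co-occurrence matrix (GLCM) texture features
    (uniformity, entropy, dissimilarity, correlation, inverse difference
    normalized) from radiologist-style regions of interest on CT volumes in
    Hounsfield units, using HU admissibility filtering and the largest tumor
    cross-section, and relates them to overall survival through rank-sum
    comparison, univariate Cox regression with Wald tests, ROC analysis with
    Youden thresholds, and median-split Kaplan-Meier curves. Includes a
    synthetic phantom cohort generator with spatially correlated texture and
    proportional-hazards survival so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'GLCMSurv-package.R'
    'image_io.R'
    'survstats.R'
    'texture.R'
    'pipeline.R'
    'synthetic.R'
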