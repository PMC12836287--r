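Package: dosemimic
Title: Atlas-Based Dose Prediction and Complete-Block Generation for
    Helical Tomotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deformable-image-registration (DIR) based dose mimicking for
    left-sided breast radiotherapy. Predicts a patient-specific 3D low-dose
    distribution from an atlas of tangential-arc reference plans by
    SSIM-weighted fusion of deformably warped doses, derives a personalized
    "complete block" avoidance structure from the predicted 2-Gy isodose
    volume, and evaluates plans with DVH metrics, conformity and homogeneity
    indices, integral dose, Dice overlap, and a non-parametric statistical
    harness with Holm-Bonferroni correction. Includes a seeded thorax-phantom
    cohort simulator, a two-stage (affine then B-spline) intensity-based
    registration engine, readers and writers for DICOM-RT (CT series,
    RTDOSE, RTSTRUCT) and a MetaImage research volume format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
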