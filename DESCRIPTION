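Package: dwiresponse
Title: Multi-Model Diffusion-Weighted MRI Analysis for Treatment-Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward signal models, voxelwise fitting and cohort-level
    statistics for multi-b-value diffusion-weighted MRI (DWI) of tumors.
    Implements the mono-exponential (Gaussian, ADC), intravoxel incoherent
    motion (IVIM: D, D*, f) and stretched-exponential (DDC, alpha) decay
    models; log-linear and bounded non-linear least-squares parameter
    estimation per voxel with goodness of fit; area-weighted
    volume-of-interest aggregation of region-of-interest slice means;
    RECIST-style tumor response classification from longitudinal diameter
    series; and the statistics layer used to compare imaging biomarkers
    between responder groups (Lin's concordance correlation coefficient,
    pooled-variance t tests, chi-square/Fisher tests, empirical ROC with
    Youden cutoff and DeLong AUC comparison). A synthetic phantom and
    cohort generator with Rician noise makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
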