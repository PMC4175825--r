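Package: voxelprog
Title: Voxel-Wise Logistic Modelling of Glioma Progression from
    Multiparametric CT-Perfusion and FDG-PET Maps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Relates co-registered CT-perfusion maps (blood flow, blood
    volume, permeability-surface area product) and FDG-PET maps
    (body-surface-area normalised standard uptake value and its ratio to
    blood flow) to MR-defined tumour progression in malignant glioma.
    Builds per-patient bounding-box voxel tables, fits pooled voxel-wise
    logistic regressions by iteratively reweighted least squares with
    odds-ratio and probability reporting, produces leave-one-patient-out
    cross-validated probability maps with ROC and Youden-index
    evaluation, and compares models with Friedman and exact Wilcoxon
    signed-rank tests.  A synthetic multiparametric cohort generator
    with known voxel-level ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    EBImage,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
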