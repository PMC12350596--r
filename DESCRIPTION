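Package: hepafunc
Title: Liver Function Estimation from Multiphase Hepatic CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating liver functional reserve from routine
    multiphase hepatic CT. Computes iodine-uptake biomarkers (extracellular
    volume fraction, iodine washout rate), body-surface-area-normalized
    hepatosplenic volumetry, and technetium-99m-GSA scintigraphy indices
    (HH15, LHL15); evaluates them against the indocyanine green retention
    test (ICG-R15) with ROC analysis, Youden thresholds, DeLong AUC
    comparisons, Spearman correlations, Welch and Fisher tests, and
    intraclass correlation coefficients; and classifies severe liver
    dysfunction (ICG-R15 >= 20%) with a combined logistic diagnostic model.
    Includes a seeded synthetic-cohort and voxel-phantom generator so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
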