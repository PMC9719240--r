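Package: fetrad
Title: Radiomics-Based Survival Prediction for Amino-Acid PET Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for survival prediction from
    static amino-acid PET images of brain tumors. Provides synthetic PET
    phantom cohorts with planted proportional-hazards survival signal,
    tumor-to-background-ratio (TBR) threshold segmentation of volumes of
    interest, fixed-bin-width intensity discretization, a 107-feature
    radiomics engine spanning first-order, shape and five gray-level texture
    matrix classes, PCA-based feature-set construction, univariate Cox and
    Kaplan-Meier screening, and random-forest survival classification and
    regression evaluated under cross-scanner testing scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ranger,
    igraph,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
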