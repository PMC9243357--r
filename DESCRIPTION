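Package: crsradiomics
Title: CT Radiomics Pipeline for Predicting Histopathologic Response to
    Neoadjuvant Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an end-to-end CT-radiomics workflow for predicting
    the dichotomized chemotherapy response score (CRS1-2 vs CRS3) of omental
    tumor deposits in high-grade serous ovarian carcinoma from pre-treatment
    contrast-enhanced CT. Provides 3D radiomic feature extraction (shape,
    first-order, GLCM, GLRLM, GLSZM, GLDM, NGTDM; 107 features) with
    Hounsfield-unit resegmentation and Freedman-Diaconis gray-level
    quantization, Hounsfield-threshold tissue sub-segmentation and tumor
    volumetry, leakage-safe nested cross-validated Elastic Net logistic
    modeling with an embedded supervised redundancy filter, occurrence-count
    stability selection yielding a compact interpretable signature,
    majority-voting ensemble prediction for external cohorts, and
    imbalance-aware evaluation (G-mean, PPV/NPV) with non-parametric
    comparisons. A synthetic-data module generates lesion phantoms and
    feature-table cohorts with known ground truth so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
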