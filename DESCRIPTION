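Package: sliceomics
Title: Slice-Spacing-Aware Radiomics Signatures for 1p/19q Co-Deletion Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end radiomics pipeline for studying how MRI inter-slice
    spacing affects machine-learning signatures of chromosomal 1p/19q
    co-deletion in lower-grade glioma. Provides a seedable synthetic 3D image
    cohort generator, NIfTI volume and ROI handling, intensity normalization
    and a strided slice-retention down-sampler that emulates conventional
    thick-interval acquisitions, a from-scratch extractor for 107 shape,
    first-order and texture (GLCM, GLRLM, GLSZM, GLDM, NGTDM) radiomics
    features, LASSO plus random-forest signature construction with
    importance-based feature reduction, DeLong confidence intervals and the
    paired DeLong test for correlated ROC curves, subgroup re-evaluation, and
    occlusion sensitivity maps for individual radiomics features.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    glmnet,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
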