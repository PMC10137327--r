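Package: selectmri
Title: Confidence-Aware Selective Evaluation of MRI Radiogenomic Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study whether multimodal brain-MRI classifiers of MGMT
    promoter methylation carry usable signal once prediction confidence is
    taken into account. Provides a synthetic multimodal 3D cohort generator
    with BraTS-convention tumour phantoms and a tunable radiogenomic signal,
    volume preprocessing (non-zero-voxel standardization, volumetric CLAHE,
    tumour-ROI extraction, augmentation), a small trainable 3D residual
    convolutional classifier with early, intermediate and late fusion,
    four per-sample confidence scores (maximum softmax probability,
    temperature-scaled input perturbation, a trained confidence branch and
    an attribution-resilience score), a methylation-percentage surrogate
    confidence metric, and percentile-thresholded selective evaluation with
    ROC/PR reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
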