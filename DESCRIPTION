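Package: cranioseg
Title: Craniopharyngioma MRI Segmentation with a Non-Local U-Net and Tversky Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic segmentation of craniopharyngioma on coronal
    contrast-enhanced T1 MRI: NIfTI/DICOM input, CLAHE-based preprocessing with
    isotropic resampling, a slice-wise U-Net with an embedded-Gaussian non-local
    attention block at the bottleneck, a compound Tversky/cross-entropy training
    objective, per-case overlap and surface-distance metrics (Dice, Jaccard,
    TPR, FPR, 95th-percentile Hausdorff distance, volume), subgroup ANOVA,
    Bland-Altman and intraclass-correlation agreement statistics, and a
    synthetic sellar-tumor phantom generator so the full pipeline can be
    exercised without patient data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    EBImage,
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
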