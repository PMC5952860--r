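Package: cortigap
Title: Cortical Interruption and Trabecular Void Detection in HR-pQCT Joint Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated detection of cortical interruptions (the imaging
    correlate of early bone erosions) and their underlying trabecular void
    volume in high-resolution peripheral quantitative computed tomography
    (HR-pQCT) images of metacarpophalangeal joints. Provides periosteal
    auto-contouring, fixed-depth cortical masking, diameter-filtered
    interruption detection via 3D Euclidean distance transforms, void-volume
    extension by constrained morphological reconstruction, distance-transform
    bone morphometry surrogates (BV/TV, Tb.Th, Tb.Sp, Ct.Th, Ct.Po),
    reproducibility statistics (ICC(2,1) with 95% CI, RMS precision errors,
    least significant change, Bland-Altman, paired t), motion-grade stack
    exclusion logic, and a synthetic joint phantom generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    grDevices,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
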