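Package: spectreg
Title: Registration-Based Comparison of Pre- and Post-Operative Knee SPECT/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatially aligns paired SPECT/CT knee scans within and between
    subjects so that radiotracer uptake (a proxy for osteoblastic activity)
    can be compared voxel by voxel after unicondylar knee arthroplasty.
    Provides volumetric NIfTI input/output, resampling and laterality
    reflection, landmark-driven volumes of interest with threshold-based
    bone and prosthesis masking, a multiresolution registration engine
    (affine and cubic B-spline free-form transforms, Halton-sampled Parzen
    joint histograms, mutual-information metrics, adaptive stochastic
    gradient descent), uptake normalization with voxel-wise difference and
    cohort aggregate maps, Dice/landmark validation with the associated
    non-parametric tests, and a synthetic knee phantom generator with known
    ground-truth deformations for end-to-end verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
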