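Package: volve
Title: Voxel-Wise Lung Ventilation and Perfusion Mapping from
    Free-Breathing Dynamic Lung MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing of free-breathing 2D dynamic proton lung-MRI
    time series into voxel-wise ventilation-weighted and perfusion-weighted
    maps. Each lung voxel's signal time course is compared with a
    diaphragm-derived respiratory navigator (or a vessel-derived cardiac
    reference) by lagged cross-correlation and by York errors-in-variables
    regression, yielding maps of maximum cross-correlation (XCC), lag and
    regression gradient (Grad), together with classical fractional
    ventilation. Includes a synthetic dynamic lung phantom with known
    ground truth, seeded region-growing lung segmentation with automatic
    navigator-ROI placement, zero-phase band conditioning of physiological
    signals, demons-based non-rigid registration of the frame series,
    Gaussian-mixture histogram summaries (peak-area ratio, skewness) and
    repeatability statistics (Bland-Altman, coefficient of variation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    signal,
    jsonlite,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
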