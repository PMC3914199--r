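Package: retinapulse
Title: ECG-Gated Mapping and Measurement of Retinal Vessel Pulsation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Visualizes and quantifies pulsatile changes in retinal vessel
    caliber over the cardiac cycle from ECG-gated fundus image sequences.
    Provides a synthetic pulsating-vessel phantom generator with full ground
    truth, rigid inter-frame registration by phase correlation, an
    edge-enhancing vesselness map built from the gradient of the Hessian
    eigenvector orientation field, Gabor-wavelet Bayes pixel classification
    for vessel masking, seed-based edge tracking with shortest-distance
    cross-section caliber measurement and micrometer calibration,
    dynamic-time-warping alignment of per-phase diameter trends with
    repeated-measures ANOVA, and concentric-zone playback rendering around
    the optic disk.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
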