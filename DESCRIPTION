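Package: psar
Title: Periodic Split Attractor Reconstruction for Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to turn a single-lead electrocardiogram into phase-space
    density-map features by periodic split attractor reconstruction (PSAR).
    The signal is denoised with a 10-level Daubechies-6 wavelet decomposition,
    detrended with a LOESS baseline fit, delineated into PQRST fiducial
    points, split by cardiac cycle (R-R, Q-R-S or S-TP-Q), delay-embedded in
    three dimensions with a per-cycle delay of one third of the cycle period,
    projected onto the plane orthogonal to the x=y=z axis, and binned into a
    two-dimensional density map. A synthetic-signal module (ideal sinusoids
    and a parameterised PQRST generator with exact ground truth) makes every
    stage testable without any ECG archive.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
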