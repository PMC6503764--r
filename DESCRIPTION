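Package: edcal
Title: Geometry Calibration for 3D Electron Diffraction Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration computations that turn a transmission electron
    microscope with a hybrid pixel detector into a usable electron
    diffractometer. Determines the effective detector distance and
    elliptical distortion from an aluminium powder standard by direct
    least-squares ellipse fitting of ring peaks, the rotation-axis azimuth
    from the azimuthal intensity minimum of summed oscillating powder
    frames, the goniometer rotation rate and oscillation width from
    angle-versus-time logs, and dose and magnification budgets; writes an
    integration-ready geometry template. Includes a synthetic-data
    generator with known ground truth so every estimator is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
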