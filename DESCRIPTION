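Package: texchange
Title: Oscillatory EEG Correlates of Texture Change During Active Touch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the brain responds when a fingertip sweeps
    across a change in surface texture. Implements parametric synthesis of
    isotropic rough surfaces with a prescribed piecewise power spectral
    density, contact-point estimation from six-axis force/torque recordings,
    transition-locked EEG epoching, a sliding-window Welch time-frequency
    transform with median/MAD robust normalisation, and electrode-wise
    sign-flip permutation statistics with spatial clustering. A synthetic-data
    generator emulates full experimental sessions (finger kinematics, wrench
    streams, 129-channel EEG with injected event-related desynchronisation)
    so every stage is testable against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
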