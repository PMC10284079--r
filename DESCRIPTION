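Package: spadflim
Title: Calibration, Lifetime Fitting and Simulation for SPAD-Array Light-Sheet FLIM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for time-correlated single photon counting (TCSPC)
    fluorescence lifetime imaging with single-photon avalanche diode (SPAD)
    array cameras on light-sheet microscopes. Covers photon-stream and decay
    histogram data structures with an HDF5 dialect, SPAD sensor calibration
    (per-pixel dark count rate from decay tails, inter-pixel timing skew by
    circular cross-correlation, screamer/dead pixel detection), iterative
    reconvolution least-squares fitting of mono- and biexponential decay models
    with a periodic wrapped-exponential kernel, intensity-guided upscaling of
    lifetime maps with cell masking and per-cell NAD(P)H metabolic statistics,
    acquisition-speed and light-dose budget calculations, a linear trend test
    for metabolic time courses, and a seeded synthetic SPAD acquisition
    simulator for validation without the instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    minpack.lm,
    rhdf5,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
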