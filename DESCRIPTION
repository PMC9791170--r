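Package: detchar
Title: Characterization of Electron-Counting Direct Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for characterizing electron-counting direct
    detectors for cryo-EM: coincidence-loss dose-response modelling and
    exposure planning, rotationally averaged noise power spectra with
    NPS-based coincidence-loss estimation, slanted-edge modulation transfer
    function (MTF) estimation, noise-binning DQE(0) and DQE-curve synthesis,
    and ResLog (resolution versus particle number) analysis. Includes an
    event-based counting-sensor simulator that reproduces the statistical
    structure the analyses assume (Poisson arrival, per-pixel counting
    windows, coincidence loss, super-resolution event placement, false
    positives), plus minimal MRC movie input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
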