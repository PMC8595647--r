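Package: amepollen
Title: Two-Taxon Airborne Pollen Counting from Light-Scattering Signals
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates separate airborne counts of two pollen taxa from the
    overlapping forward light-scattering intensity distributions recorded by
    laser-optics particle counters (KH-3000 class instruments). Per-taxon
    Gaussian reference distributions are fitted to calibration signals, a
    2x2 linear unmixing system is solved over every enumerated pair of
    voltage integration intervals, non-negative solutions are pooled and the
    modal output adopted, and each daily estimate is scored with a
    confidence coefficient. Includes a field pipeline (side-scatter dust
    gating, conversion of signal counts to volumetric concentrations,
    comparison against gravimetric deposition counts) and a synthetic
    signal-stream generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
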