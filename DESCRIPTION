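Package: protonInterplay
Title: Interplay of Intrafraction Prostate Motion with Layered Proton Delivery
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation of the dosimetric interplay between intrafraction
    prostate motion and proton dose delivery for double-scattering (DS) and
    uniform-scanning (US) techniques. Provides an analytic spread-out Bragg
    peak (SOBP) beam model with energy-layer decomposition, a synthetic
    generator for 10 Hz three-dimensional prostate displacement traces
    (slow drifts, transient excursions, persistent offsets), per-second 4D
    dose accumulation on a rigidly moving clinical target volume, cumulative
    dose-volume histogram (DVH) metric extraction (V100, V95, V110, D100,
    D95, D5), and cohort-scale DS-versus-US comparison with paired
    significance testing, for conventional and SBRT fractionation schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
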