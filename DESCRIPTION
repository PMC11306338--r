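Package: turbikin
Title: Turbidimetric Growth-Curve Kinetics and Microwave Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for turbidimetric (optical density) protein
    polymerization assays, built around microtubule growth curves. Extracts
    per-run kinetic features (final optical density, crossing times t10/t50,
    and the early-phase power-law exponent b from a windowed log-log fit),
    compares experimental cohorts with median-absolute-deviation outlier
    rejection, Mann-Whitney U tests and a time-stretching transform, audits
    normality with a four-test battery, and estimates statistical power by
    simulation. Includes a stochastic growth-curve generator with explicit
    thermal histories (Arrhenius-scaled Avrami kinetics) and the waveguide
    dosimetry arithmetic (dBm power budget, S-parameter losses, peak field,
    specific absorption rate) needed to characterise microwave exposure
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nortest,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
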