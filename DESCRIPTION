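Package: formstress
Title: Quantitative Analysis of Bacterial Formaldehyde Stress-Response Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and model-fitting tools for the assay panel used to
    characterize formaldehyde stress physiology in methylotrophic bacteria:
    colony-forming-unit estimation from replicate serial-dilution spot
    plating, single-cell formaldehyde-tolerance frequency distributions with
    a plating limit of detection and log-linear decline-slope statistics,
    Malthusian relative fitness from flow-cytometry competition assays,
    one-site isothermal titration calorimetry and Hill-equation
    thermophoresis binding fits, colorimetric formaldehyde quantification
    with intracellular normalization, growth-curve kinetics, and
    heavy-methionine translation ratios.  Seeded synthetic-data generators
    emulate every assay so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
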