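Package: photostab
Title: Photostabilization Kinetics and Host-Guest Complexation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative workflow for cyclodextrin-assisted photostabilization
    of photolabile drugs such as 5-fluorouracil. Fits first-order photolysis
    rate constants from irradiation time courses, derives second-order
    drug-cyclodextrin interaction constants by secondary regression of kobs on
    cyclodextrin concentration, and assembles rate-pH profiles. Analyses
    fluorescence quenching by the Stern-Volmer and double-logarithmic binding
    models, computes entrapment efficiency, determines complex stoichiometry
    from Job's continuous-variation data and conductometric breakpoints,
    evaluates acid-base speciation, converts actinometric photon fluxes to
    quantum yields, and produces ICH-style calibration validation statistics
    (linearity, LOD, LOQ, accuracy, precision). Includes a seeded synthetic
    data generator emulating every input series so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
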