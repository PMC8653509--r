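Package: osmoflux
Title: Needle Micro-Osmometry of Tissue Swelling Pressure and Osmolality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers intra-tissue swelling pressure and osmolality from
    microdialysis-probe fluid flux via a radial Darcy flow model with
    strain-dependent tissue permeability, and independently computes the
    ionic (Gibbs-Donnan) component of swelling pressure from measured
    intra-tissue sodium normalized to total tissue water. Includes probe
    membrane calibration from meniscus displacement series under known
    polyethylene-glycol osmotic loads, a forward simulator for
    parameter-recovery testing, and an analysis layer with group
    summaries, linear fits, Spearman correlations and Lin's concordance
    correlation coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
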