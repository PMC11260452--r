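Package: hdcoop
Title: Cooperative Homeodomain-DNA Binding: Geometry, Thermodynamics and Motif Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying cooperative homeodomain-DNA
    binding on head-to-tail dimer sites. Provides nucleic-acid geometry
    (base-pair reference frames, step parameters, helical-axis bend, groove
    profiles and sequence-based shape features), structure comparison and
    interface analysis (least-squares superposition, solvent-accessible
    surface area, buried interface area, residue contacts), trim-and-join
    head-to-tail dimer modeling on n-bp spacers, one-site isothermal
    titration calorimetry isotherm simulation and fitting with derived
    thermodynamics, the tau cooperativity statistic under a
    two-identical-site equilibrium model for gel-shift band intensities,
    position-weight-matrix spacer-variant construction and scanning with
    per-cycle SELEX enrichment and spacer G/C composition analysis, and
    seeded synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
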