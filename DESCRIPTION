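Package: sovex
Title: Broken-and-Intact-Cell Kinetics, Mass Transfer and Cost Modelling for
    Supercritical CO2 Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling packed-bed supercritical CO2 extraction of
    plant oils. Implements the analytical broken-and-intact-cell (BIC)
    extraction model of Sovova with the three-period piecewise overall
    extraction curve, least-squares estimation of the grinding efficiency and
    the internal and external volumetric mass-transfer parameters from
    cumulative extraction curves, Sherwood-Reynolds-Schmidt correlation
    calibration with a Catchpole-King-type dense-gas diffusivity estimate,
    two-level factorial response-surface analysis of extraction yield with
    D-optimal subset selection, and a Turton-style cost-of-manufacturing model
    for scaled-up batch extraction plants. Ships the operating conditions,
    design tables and cost constants of a Pistacia lentiscus leaf extraction
    case study, plus seeded synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
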