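Package: oacf
Title: Spatially Explicit Characterization Factors for Ocean Acidification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Life-cycle impact characterization of ocean acidification from
    greenhouse-gas emissions (CO2, CO, CH4). Chains an atmospheric dissolution
    pathway, a Revelle-factor carbonate fate model on regionally averaged
    gridded ocean fields, per-region pH-on-spCO2 fate sensitivity regressions,
    logistic dose-response fits of species experiments, and species
    sensitivity distributions into regionalized midpoint (pH yr/kg) and
    endpoint (PDF yr/kg) characterization factors, with area-weighted global
    aggregation and CO2-equivalent normalization. Includes synthetic
    generators for gridded fields, region partitions and species experiments
    that emulate the statistical structure of the observational inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
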