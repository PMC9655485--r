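Package: milkteq
Title: Toxic Equivalents and Lactation-Stage Analysis of PCB Residues in
    Human Milk
Version: 0.1.0
Authors@R:
    person("Milkteq", "Developers", email = "milkteq@example.org",
           role = c("aut", "cre"))
Description: Tools for dietary exposure assessment of polychlorinated
    biphenyls (PCBs) in human-milk biomonitoring studies. Converts
    congener-level concentrations between wet-weight and lipid basis,
    handles left-censored values below detection or quantification limits,
    computes WHO toxic-equivalency-factor weighted toxic equivalents (TEQ),
    summarises concentrations across lactation stages, fits redundancy
    analysis (constrained ordination) of congener profiles on maternal
    covariates, estimates infant weekly intake against the tolerable weekly
    intake, screens samples against EU maximum levels for foods for infants
    and young children, and generates seeded synthetic mother/infant/milk
    cohorts with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
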