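Package: kinepistasis
Title: Cryptic Epistasis in Enzyme Kinetic Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of non-specific ("cryptic") epistasis
    that is intrinsic to enzyme catalytic cycles. Free-energy profiles of
    Michaelis-Menten style mechanisms are converted to microscopic rate
    constants via transition-state theory; additive free-energy
    perturbations ("mutations") are combined into double mutants and their
    kinetic parameters are compared against a multiplicative null model.
    Includes a closed-form epistasis surface for the Michaelis constant,
    epistasis classification (magnitude, sign, reciprocal sign), and a
    correction workflow that separates specific from non-specific epistasis
    in measured microscopic rate constants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
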