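Package: mgff
Title: Magnesium Ion Force-Field Parametrization Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and validating Lennard-Jones parameters of
    Mg2+ (and the Cl- reference ion) for biomolecular simulations in
    different rigid water models. Ships the published microMg/nanoMg
    parameter registry with scaled Lorentz-Berthelot combination-rule
    algebra and GROMACS topology export, the ion solvation free-energy
    correction stack (finite-size, compression and interfacial-crossing
    terms), estimators for hydration-shell structure, water-exchange
    kinetics, Kirkwood-Buff activity derivatives and umbrella-sampling /
    alchemical free energies, the three-step grid-search parameter
    selector, and seeded synthetic-data generators with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
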