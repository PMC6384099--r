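Package: fermstoich
Title: Stoichiometric Accounting for Anaerobic Fermentation Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Net substrate and product accounting, molar yields, carbon
    recovery, degree-of-reduction electron recovery, and redox cofactor
    (NADH/ferredoxin/ATP) ledgers for batch fermentations of solventogenic
    clostridia.  Built around the IBE (isopropanol-butanol-ethanol)
    fermentation of d-glucose and the bacterial-microcompartment-mediated
    catabolism of l-rhamnose to 1,2-propanediol, n-propanol and propionate
    by Clostridium beijerinckii, with a compound registry (elemental
    formulas, CO2 classes), declarative pathway definitions, packaged
    reference cultures, and a seeded synthetic time-course generator with
    known ground-truth stoichiometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
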