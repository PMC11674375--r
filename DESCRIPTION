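Package: glycoren
Title: Proteomics-Constrained Kinetic Modeling of Renal Glucose Metabolism
Version: 0.1.0
Authors@R:
    person("glycoren", "maintainers", email = "glycoren@example.org", role = c("aut", "cre"))
Description: Kinetic ODE model of renal glucose metabolism covering glycolysis,
    gluconeogenesis and the polyol pathway, with the Rapoport-Luebering shunt
    (2,3-bisphosphoglycerate mutase and phosphatase) and configurable
    2,3-bisphosphoglycerate feedback on hexokinase and phosphoglycerate mutase.
    Maximal enzyme activities are scaled per sample from quantitative proteomics
    intensity tables (Vmax proportional to protein abundance relative to the
    control-group mean), sample-specific models are integrated to steady state
    over a grid of external glucose concentrations, and control versus knockout
    ensembles are compared as mean and standard deviation of glucose and lactate
    exchange fluxes. Includes a seeded synthetic proteomics generator
    (group-structured lognormal noise with a configurable Bpgm knockdown) and
    analytic toy models so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
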