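Package: dynlogic
Title: Dynamic Simulation of Genetic Logic Circuits Driven by Metabolic Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and simulates combinatorial genetic logic circuits that
    integrate Escherichia coli metabolic sensors (glucose, dissolved oxygen,
    acetate) to implement dynamic control of gene expression during batch
    growth. Provides Hill transfer functions and dose-response fitting for
    sensors, steady-state response functions and ODE dynamics for NOT/NOR,
    AND and ANDN gates wired into acyclic netlists, truth-table digitization
    and bounded-depth circuit enumeration, a combinatorial designer for
    operator-embedded constitutive promoter libraries with synthesis-QC
    screens, kinetic models of CRISPRi, sRNA and targeted-protease
    knockdowns, and a synthetic-data generator emulating batch fermentation
    stimulus trajectories, noisy dose-response measurements and cytometry
    populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    minpack.lm,
    deSolve,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
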