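Package: gbasolve
Title: Growth Balance Analysis for Coarse-Grained Self-Replicating Cell Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Construct, validate, and numerically solve coarse-grained growth
    balance analysis (GBA) models of self-replicating cells. A GBA model couples
    a mass-fraction stoichiometric matrix, convenience-kinetics rate laws
    (irreversible or reversible, with activation and inhibition), and a total
    cell-density constraint; solving the resulting nonlinear program predicts
    the optimal growth rate, reaction fluxes, metabolite concentrations, and
    whole-proteome allocation in each growth condition, without requiring the
    biomass composition as an input. Models are exchanged as ODS spreadsheets
    or CSV bundles; the package also provides a validation pipeline with
    automatic Michaelis-constant repair, a synthetic model generator,
    parameter-lumping helpers for coarse-graining, tidy result tables, static
    condition-sweep plots, a GraphML flux-map export, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
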