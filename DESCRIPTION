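Package: immunecol
Title: Ecological Dynamics of Tumor-Immune Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of predator-prey models of tumor-immune
    ecology: Holling-type functional responses, the Lotka-Volterra system and
    its conserved quantity, a generalized prey model with Allee threshold,
    carrying capacity and predator injury, and a minimal three-compartment
    tumor/effector/antigen-presenting-cell model with quasi-steady-state
    reduction.  Includes equilibrium and linear-stability analysis, dynamical
    regime classification over a predator-inefficiency parameter plane
    (paralleling the elimination/equilibrium/escape phases of cancer
    immunoediting), and interaction-matrix diagnostics that classify pairwise
    community modules (predator-prey, competition, mutualism, commensalism,
    amensalism) from local effect signs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
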