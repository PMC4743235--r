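Package: peritree
Title: Fractal Peripheral-Resistance Outflow Boundary Conditions for
    Carotid Blood-Flow Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates zero-dimensional (0D) peripheral-resistance outflow
    boundary conditions for truncated arterial blood-flow models of the
    carotid bifurcation and the external carotid branches.  The peripheral
    vasculature downstream of each imaged outlet is represented as a
    symmetric fractal binary tree governed by a minimum-energy power law,
    with per-generation vessel-group classification, length-to-radius
    ratios taken from anatomical group averages, and a diameter-dependent
    apparent blood viscosity capturing the Fahraeus-Lindqvist effect.
    Resistances are reduced by a Poiseuille series/parallel recursion and
    the terminal resistance is adjusted so that the capillary-level
    pressure matches a physiological target.  A lumped Poiseuille
    surrogate of the imaged domain allows the three classical outflow
    variants (zero pressure, constant length-to-radius ratio, and the
    structured peripheral model) to be coupled, solved and compared end to
    end, together with a seeded generator of carotid-like synthetic outlet
    sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
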