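Package: fermkin
Title: Batch Fermentation Kinetics: Simulation, Descriptors, Monod Fitting
    and Condition Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for batch ethanol fermentation time courses.
    Provides a mechanistic generator of synthetic batch time courses (Monod
    growth with optional Andrews substrate inhibition and product toxicity,
    Luedeking-Piret product formation, yield/maintenance substrate balance,
    cardinal-pH and salinity stress modifiers), the standard per-condition
    kinetic descriptors (peak ethanol and biomass, yield coefficients,
    volumetric productivity, substrate uptake, specific rates), nonlinear
    least-squares fitting of the Monod saturation model relating specific
    rates to initial substrate concentration with a parameter-recovery
    harness, and a condition-comparison layer (one-way ANOVA, Tukey HSD,
    compact letter displays, optimum identification) for factorial studies
    over initial glucose, salinity and pH.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
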