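Package: crystagg
Title: Kinetics of Redox-Coupled Gamma-D-Crystallin Aggregation and Its
    Suppression by Myo-Inositol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic modelling and statistical analysis of the
    oxidative aggregation of cataract-associated human gamma-D-crystallin
    variants and its suppression by the lens metabolite myo-inositol.
    Provides a redox-coupled ODE aggregation simulator with an inositol-
    inhibited bimolecular dimerization step, tangent-method turbidity trace
    statistics (maximum rate, apparent lag, phase segmentation), power-law
    concentration-dependence and dose-response analysis, glutathione redox
    arithmetic (degree of oxidation, speciation), PEGylation gel-band
    simulation, aggregate morphometry statistics, and a seeded synthetic
    plate-reader data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
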