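Package: ippspec
Title: Speciation, NMR Titration and Binding Thermodynamics of Inositol
    Pyrophosphates
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the solution chemistry of highly phosphorylated
    inositol messengers (InsP6, 5PCP-InsP5, InsP8).  Provides a chemical
    model registry of protonation and K+/Mg2+ formation constants, a
    damped-Newton mass-balance solver for species distribution diagrams,
    a fast-exchange 31P-NMR titration fitter that refines cumulative
    formation constants and species-limiting shifts by separable
    (variable-projection) least squares, van't Hoff and Gibbs-Helmholtz
    analysis of the axial/equatorial ring-flip equilibrium, a one-site
    isothermal titration calorimetry simulator and fitter, and seeded
    synthetic-data generators so the whole pipeline is testable without
    instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
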