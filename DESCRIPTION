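Package: chankit
Title: Single-Channel Recording Analysis for Planar Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single ion-channel recordings from planar
    lipid bilayer (black lipid membrane) experiments: stochastic simulation
    of channel gating (Poisson openings, exponential-mixture open lifetimes,
    Gaussian unit conductance, optional stacked openings and burst episodes),
    half-amplitude threshold idealization of current traces into event
    tables, conductance probability histograms with Gaussian fits of the
    central conductance, open-lifetime survival analysis with one- or
    two-exponential least-squares fits and extra-sum-of-squares F-test model
    selection, Goldman-Hodgkin-Katz reversal-potential and permeability-ratio
    calculations, and two-compartment radiotracer permeability coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
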