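Package: stackprobe
Title: Global TCSPC Decay Fitting and Exciton CD Analysis for
    2-Aminopurine DNA Probes
Version: 1.0.0
Authors@R:
    person("stackprobe", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools to quantify DNA conformational heterogeneity from
    2-aminopurine (2AP) spectroscopy.  Implements iterative-reconvolution
    fitting of multi-exponential time-correlated single photon counting
    (TCSPC) fluorescence decays with lifetimes linked globally across
    emission wavelengths, model-order selection, parametric-bootstrap
    uncertainties and residual diagnostics; processing of low-energy
    exciton-coupled circular dichroism (CD) spectra (scan averaging,
    blank subtraction, moving-average smoothing, conversion to molar CD
    per 2AP residue) and exciton amplitude metrics; translation of fit
    parameters into stacked / partially stacked / extrahelical
    conformational populations and between-condition percentage changes;
    and a seeded synthetic-data generator so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
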