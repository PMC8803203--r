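Package: tissuelight
Title: Tissue Optical Property Estimation from Integrating-Sphere Measurements
Version: 0.1.0
Authors@R: person("Omar", "Farouk", email = "ofarouk@example.org", role = c("aut", "cre"))
Description: Estimates tissue absorption and reduced scattering coefficients
    from integrating-sphere diffuse reflectance and transmittance via the
    Kubelka-Munk two-flux model, derives the optical penetration depth,
    simulates steady-state surface fluence-rate distributions with the
    diffusion approximation, verifies scattering behaviour with slab photon
    Monte Carlo at varying anisotropy, and quantifies between-condition
    discrimination with empirical ROC/AUC statistics. Includes a synthetic
    spectrometer-data generator that emulates 808 nm integrating-sphere
    measurements so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
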