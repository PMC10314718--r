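Package: simeval
Title: Stochastic Image Models and Pertinent-Statistic Evaluation of
    Generative Image Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Seeded simulators for three canonical stochastic image models
    used in medical image quality research - the clustered lumpy background
    (mammographic texture), B-mode ultrasound speckle at configurable
    scatterer number density, and a stylized two-dimensional breast-slice
    model with X-ray attenuation assignment - together with the per-image
    and ensemble statistics pertinent to each: seventeen texture features
    (first-order, co-occurrence, run-length and neighborhood gray tone
    difference families), intensity signal-to-noise ratio and
    scatterers-per-resolution-cell estimates, fat-to-glandular tissue
    ratios, gray-level probability density functions and Papoulis-windowed
    radial autocorrelation.  A comparison harness scores a candidate image
    ensemble (for example, output of a trained generative model) against a
    reference model by Jensen-Shannon divergence of these statistics, with
    matched noise floors computed from independent reference draws.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
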