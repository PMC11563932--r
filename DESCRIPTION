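Package: lungpdt
Title: Light Dosimetry for Whole-Lung Photodynamic Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo light dosimetry for perfusion-assisted
    photodynamic therapy (PDT) of the whole lung. Provides a voxel
    photon-packet transport engine with Henyey-Greenstein scattering and
    track-length fluence scoring, a synthetic thorax phantom generator
    with LED disc sources and isotropic fibre detectors,
    diffusion-approximation closed forms for validation, dose-volume
    histograms and effective-attenuation fits, and photodynamic-threshold
    determination with dose-escalation and lung-toxicity bookkeeping.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
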