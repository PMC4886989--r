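Package: sfxprep
Title: Pre-Processing Pipeline for Serial Femtosecond Crystallography Detector Data
Version: 0.1.0
Authors@R:
    person("SFX", "Maintainers", email = "sfxprep@example.org", role = c("aut", "cre"))
Description: Desk-scale re-implementation of a serial femtosecond
    crystallography (SFX) pre-processing pipeline for a multi-module
    CCD detector: dark-reference construction and conversion of raw
    ADU frames to photon-normalized 16-bit images, Bragg spot finding
    by thresholding and connected components with area and
    signal-to-noise filters, low-level blank rejection and spot-count
    hit classification, multi-event HDF5 output with per-pulse tag
    groups and deflate compression, streaming hit-rate monitoring,
    a producer-consumer tag-completeness dispatcher, and grid search
    over spot-finding parameters.  A built-in synthetic frame
    generator with per-frame ground truth replaces beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rhdf5,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
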