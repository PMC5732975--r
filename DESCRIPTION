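Package: assrdeconv
Title: Deconvolution and Synthesis of 40 Hz Auditory Steady-State Responses
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing the linear-superposition account of the 40 Hz
    auditory steady-state response (ASSR). Builds jittered (CLAD) and
    multi-rate (MSAD) stimulus sequences, simulates sweep-level EEG from
    ground-truth transient auditory evoked potential (AEP) templates,
    recovers transient templates by frequency-domain inverse filtering and
    by regularized fold-matrix inversion (truncated SVD / Tikhonov),
    synthesizes steady-state responses from templates, and compares
    synthetic against recorded responses with pointwise t-tests and
    one-sample Hotelling T-squared statistics on harmonic vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
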