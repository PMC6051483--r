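Package: lfpdec
Title: Unsupervised Feature Extraction and Decoding for Multichannel Local
    Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting low-dimensional, decodable features from
    multichannel low-frequency local field potential (LFP) recordings.
    Implements multiple-input single-output (MISO) linear system
    identification of spike-related slow potentials (SRSPs), their
    principal-component decomposition and source projections, real-time
    capable firing-rate estimation from LFP alone by Wiener deconvolution
    realized as FIR filter banks, rotational-dynamics extraction (jPCA-style
    skew-symmetric fits), planar / pairwise / banded areal-velocity signals,
    the three-dimensional areal-velocity vector, submovement detection from
    cursor kinematics, speed-proportionality analysis, and submovement
    direction decoding with an angular coefficient of determination and
    permutation control. Includes a seeded synthetic-data generator with
    ground truth so every pipeline stage is testable without external
    recordings, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
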