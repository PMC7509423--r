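Package: pvrnnagency
Title: Predictive-Coding Variational Recurrent Networks for Multimodal
    Imitative Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a multimodal predictive-coding / active-inference
    model built from variational recurrent networks (PV-RNN) with
    multiple-timescale leaky-integrator dynamics, per-layer meta-prior
    weighted complexity regulation, a static convolutional codec for pixel
    observations, offline training by backpropagation through time, and
    online posterior inference by error regression in a shifting window.
    Includes a synthetic visuo-proprioceptive sequence generator driven by
    a probabilistic finite state machine over movement primitives, and
    desk-scale experiment runners for modality-specific complexity
    regulation and meta-prior sweeps modulating the strength of agency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
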