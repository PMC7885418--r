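Package: myodecode
Title: Simultaneous and Proportional Myoelectric Decoding from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for calibrating and evaluating myoelectric control
    interfaces that decode wrist and hand kinematics from multichannel
    surface electromyography (sEMG). Implements a representation-learning
    decoder: a shared-encoder multitask feed-forward network trained on
    signal envelopes with categorical movement labels, input corruption and
    contractive (Jacobian) regularization, so that the calibrated model
    emits continuous, proportional and simultaneous estimates for several
    degrees of freedom. Also provides the standard motion-normalized
    proportional pattern-recognition benchmark (Hudgins time-domain
    features with linear discriminant analysis), a synthetic sEMG generator
    emulating an 8-channel armband acquisition protocol, a closed-loop
    Fitts's-law target-acquisition simulator with a scripted user, and the
    associated performance metrics (completion rate and time, path
    efficiency, overshoot, throughput, index-of-difficulty regression and
    Cohen's d effect sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
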