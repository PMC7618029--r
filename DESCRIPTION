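Package: pcnd
Title: Energy-Based Novelty Detection with Predictive Coding Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of recognition memory (familiarity discrimination) built on
    predictive coding. Fits a recurrent predictive coding network with local
    Hebbian learning and a hierarchical predictive coding network with iterative
    inference, and reads out the post-training energy of a query as its novelty
    signal. Includes classical and modern-continuous Hopfield energies and
    parameter-matched (variational) autoencoder baselines, the closed-form
    metric-learning description of the converged recurrent network, and an
    experimental harness for two-alternative forced-choice capacity curves,
    repetition-suppression traces and layer-wise d-prime separability, together
    with synthetic generators for correlated Gaussian patterns and
    class-structured images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
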