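Package: thzsep
Title: Scattering Correction, Parallel ANN Stability and Linear Separability
    for Featureless Terahertz Extinction Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a small feedforward neural network can
    identify featureless terahertz extinction spectra, developed around the
    three-class gelatin authentication problem (donkey, bovine, porcine skin).
    Provides a calibrated synthetic-spectrum generator with a multiplicative
    gain / additive offset scatter model, time-domain pulse synthesis and
    extinction-coefficient extraction, multivariate scattering correction (MSC),
    a from-scratch three-layer network trained by full-batch gradient descent
    with momentum, a parallel-model prediction-stability protocol with special
    train/test partitions, and separability diagnostics: PCA explained variance,
    Fisher scatter matrices with the generalized Rayleigh quotient, and a
    linear-separability index defined as the reciprocal of the minimum number
    of straight lines needed for error-free two-dimensional classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
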