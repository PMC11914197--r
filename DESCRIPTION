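Package: dpcrvar
Title: Uncertainty Estimation for Digital PCR Partition Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point estimation and uncertainty quantification for digital PCR
    (dPCR) experiments from partition counts. Implements Poisson-based
    estimators for absolute quantification, copy number variation (singleplex
    and duplex), fractional abundance and DNA integrity, together with three
    variance and confidence-interval engines: a parametric binomial bootstrap
    (BinomVar), a nonparametric replicate-based estimator with Student-t
    intervals (NonPVar), and the classical delta method. Also provides the
    exact partition-occupancy distribution (Stirling numbers of the second
    kind, with a Lambert-W asymptotic for large molecule counts) as a
    correctness oracle, a generative simulator of common dPCR error sources
    (pipetting error, partition loss, partition-volume variation,
    misclassification), and a Monte-Carlo benchmark harness computing
    empirical coverage and bias of the variance estimators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
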