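Package: pdetect
Title: Multinomial Processing-Tree Analysis of Perceptual Detection Rating Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the perceptual-detection (PD) multinomial processing-tree
    model to two-condition (target-present / target-absent) confidence-rating
    count tables. Provides the forward tree model and multinomial simulation,
    closed-form and numerical maximum-likelihood estimation with
    likelihood-ratio goodness of fit, exact Bayesian estimation by population
    parameter mapping (Dirichlet posterior sampling with coherence checking),
    Markov chain Monte Carlo sampling under uniform priors, the model's
    two-limb ROC geometry with area-based detection measures, an
    unequal-variance Gaussian signal-detection baseline, and Monte Carlo
    machinery for estimator-accuracy benchmarking, pooling-versus-averaging
    comparisons, and shrinkage-adjusted individual-observer estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
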