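Package: triconf
Title: Confidence Models for Three-Alternative Categorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian observer models of decision confidence in
    three-alternative visual categorization. Implements a generative
    observer with Gaussian sensory noise and Dirichlet decision noise,
    four confidence read-out rules (Max, Difference, Entropy, Ratio),
    Monte-Carlo response probabilities, maximum-likelihood fitting of
    individual subjects, AIC/BIC model comparison with bootstrapped
    group-summed differences, model-recovery analysis, sliding-window
    psychometric curves and hexagonal-bin confidence maps, and a
    synthetic-observer data generator emulating three experiment
    designs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
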