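Package: facemaxent
Title: Maximum-Entropy and Restricted Boltzmann Machine Models of Facial
    Landmark Preference Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised generative modelling of sculpted facial-landmark
    fluctuation data. Fits Maximum-Entropy models of interaction order one to
    three (closed-form Gaussian inference on a rank-deficient support,
    moment-matching gradient ascent for third-order couplings) and a
    Gaussian-Bernoulli Restricted Boltzmann Machine with annealed importance
    sampling normalisation; classifies the sculpting subject's gender by
    generative likelihood-ratio scores with ROC analysis and Random-Forest
    and principal-component baselines; decomposes inferred pairwise couplings
    into longitudinal and torsion components per landmark pair with bootstrap
    significance. A synthetic-data generator reproduces the statistical
    structure of the study (exact linear constraints, subject-level variance
    structure, class differences planted at a chosen interaction order) so
    the whole pipeline is testable without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
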