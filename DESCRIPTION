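Package: prevcomb
Title: Disease Prevalence Estimation from Two Error-Prone Case-Ascertainment Sources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates disease prevalence by combining two error-prone
    population-based case-ascertainment sources (for example administrative
    health records and electronic medical records). Implements rule-based OR
    and AND combination, the Rogan-Gladen sensitivity-specificity adjusted
    (RSSA) correction, and a probabilistic sensitivity-specificity adjusted
    (PSSA) Bayesian latent-class model with a probit outcome model fit by
    Gibbs sampling, together with Gelman-Rubin and DIC diagnostics,
    tetrachoric correlation, a Gaussian-copula simulation engine for
    correlated binary disease markers and misclassified source indicators,
    and a replication framework that evaluates relative bias and mean
    squared error of the estimators over grids of simulation conditions.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
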