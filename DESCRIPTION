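Package: gxetradeoff
Title: Bias-Variance Tradeoffs for Context-Dependent Genetic Effect Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding between additive (pooled) and context-specific
    (gene-by-environment, GxE) estimation of allelic effects on complex traits.
    Implements the closed-form mean-squared-error decision rule comparing the
    pooled ordinary-least-squares estimator with stratified per-context
    estimators, a screening procedure for two-context GWAS summary statistics,
    a simplified multivariate adaptive shrinkage model (mixture of zero-centered
    bivariate normal priors fit by expectation-maximization), a
    pervasive-amplification GxDiet simulation with top-hits classification, and
    a polygenic-score simulation comparing additive, stratified, and
    empirical-Bayes shrinkage scoring strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
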