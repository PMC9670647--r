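Package: phescreen
Title: Graph-Theoretical Exposome-Wide Screening of County-Level Mortality Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ecological screening pipeline for relating a county-level
    mortality outcome (deaths per 100,000 live births) to a high-dimensional
    public-health exposome table. Implements outcome-ratio construction with a
    minimum-births inclusion rule, variable reduction via an autocorrelation
    graph and an exact minimum dominating set, name-pattern elimination of
    margin-of-error variables, supervised domain-stratified correlation
    screening, unsupervised paraclique extraction from thresholded correlation
    graphs, and Bayesian-network identification of direct predictors by greedy
    hill-climbing on the Gaussian BIC score. Includes a synthetic-data
    generator with planted correlation blocks, latent-factor clusters, and
    Poisson death counts so the full pipeline is testable without restricted
    vital-records data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
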