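Package: mtmenue
Title: Bayesian Multi-Trait Multi-Environment Analysis of Nitrogen Use
    Efficiency Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gibbs sampling for multi-trait multi-environment (MTME) linear
    mixed models of incomplete-block (lattice) variety trials, aimed at the
    nitrogen use efficiency components of maize: N-uptake efficiency (NUpE)
    and N-utilization efficiency (NUtE) evaluated under contrasting soil N
    levels. Genotype effects carry an unstructured trait-by-environment
    covariance matrix (genotype-by-environment interaction); replicate, block
    and residual effects carry per-environment trait covariances, all with
    inverse-Wishart priors. Includes a lattice-trial simulator with known
    truth, plot-table ingestion and NUE trait construction, posterior
    summaries of broad-sense heritability, genetic correlations, coefficients
    of variation and HPD intervals, DIC comparison of full (interaction)
    versus null (no interaction) models, Geweke convergence checks, and
    breeding-value ranking with top-k coincidence reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    MASS,
    coda,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
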