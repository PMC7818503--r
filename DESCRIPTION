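Package: bnhm
Title: Bayesian Binomial-Normal Hierarchical Meta-Analysis of Sparse-Event Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Random-effects meta-analysis of two-arm trials with binary
    outcomes when the trials are few, small, and zero-event arms are
    common.  Fits the binomial-normal hierarchical model on the log odds
    ratio scale with a self-contained adaptive Metropolis-within-Gibbs
    sampler, so no continuity corrections enter the likelihood.  Ships a
    registry of twelve between-study heterogeneity priors (gamma on the
    precision, uniform on log tau^2, on tau^2 and on tau, half-normal on
    tau and tau^2, and the empirical DuMouchel shrinkage prior) with
    densities, quantiles and samplers on the tau scale, split-Rhat and
    effective-sample-size convergence diagnostics, an arm-level trial
    simulator for sparse-event scenarios, and a coverage/bias evaluation
    pipeline for comparing heterogeneity priors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    coda,
    jsonlite,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
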