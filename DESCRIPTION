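Package: ncrm
Title: Nonparametric Bayesian Continual Reassessment Method for Phase I
    Dose-Finding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dose-finding for single-agent phase I trials without a
    parametric dose-toxicity curve. A Dirichlet process prior is placed on
    the monotone dose-toxicity distribution function, the joint posterior of
    the per-dose toxicity probabilities and the prior hyperparameters is
    explored with an adaptive rejection Metropolis sampling (ARMS) within
    Gibbs sampler, and a two-stage adaptive design escalates or de-escalates
    one dose level at a time using posterior threshold rules. Classical
    one-parameter continual reassessment method (CRM) comparators (empiric
    power and one-parameter logistic models) with indifference-interval
    skeletons are included, together with a replicated-trial simulator that
    reports operating characteristics (MTD selection probabilities, patient
    allocation, toxicity burden).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
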