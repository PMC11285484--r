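Package: socdisc
Title: Simulation and Analysis of Social Discounting Choice Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for two-alternative social discounting experiments in
    which participants trade a selfish monetary payoff against a shared
    generous one across social distances. Provides a synthetic-data
    generator with known ground truth (hyperbolic discounting plus softmax
    choice noise, response times from a drift-diffusion process, fast-guess
    and skipped-trial contamination), model-free prosociality estimation
    (logistic indifference points and normalized trapezoidal area under the
    discounting curve), hyperbolic discount-function fitting by least
    squares and by trial-level softmax maximum likelihood, a hierarchical
    Bayesian drift-diffusion model with sex-by-condition group regressors
    (Wiener first-passage likelihood, adaptive MCMC, rank-normalized split
    R-hat, highest density intervals), and the between-subject design
    statistics layer (two-way Type II ANOVA with generalized eta squared,
    one-sample t with Cohen's d, noncentral-F power and a priori sample
    size).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    car,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
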