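Package: crisishmm
Title: Multilevel Bayesian Hidden Markov Models for Experience-Sampling
    Crisis Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, Bayesian estimation and reporting tools for
    multilevel (mixed-effects) hidden Markov models of intensive
    longitudinal experience-sampling data with multivariate Gaussian
    emissions. Generates synthetic beep-design panels with patient-level
    heterogeneity and beep-level missingness, fits the multilevel HMM by
    Metropolis-within-Gibbs MCMC with forward-filtering backward-sampling
    of latent state paths, selects the number of latent states by AIC,
    checks convergence (Gelman-Rubin), fit (posterior predictive checks,
    one-step-ahead pseudo-residuals), decodes per-patient state
    trajectories with the Viterbi algorithm, and tabulates state
    composition, staying probabilities, normalized switching
    probabilities and state occupancy at the sample and patient level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
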