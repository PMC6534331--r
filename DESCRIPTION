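Package: cbgtddm
Title: Spiking Cortico-Basal-Ganglia-Thalamic Decision Simulations and
    Drift-Diffusion Model Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-level modelling of value-based decision-making: a reduced
    striatal network with dopamine-modulated spike-timing-dependent plasticity
    tunes corticostriatal weights; a spiking cortico-basal-ganglia-thalamic
    (CBGT) network built from integrate-and-fire-or-burst neurons simulates
    choices and response times under three reward-probability conditions; and
    the simulated behaviour, together with trialwise summaries of striatal
    activity, is fit with drift-diffusion models (Wiener first-passage-time
    likelihood, adaptive Metropolis-within-Gibbs MCMC, DIC model comparison,
    flat and hierarchical variants, and neural-regressor models).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
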