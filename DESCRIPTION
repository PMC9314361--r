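Package: ctmcpsd
Title: Power Spectral Densities of Stochastic Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the power spectral density (PSD) of single-species
    copy-number trajectories of continuous-time Markov chain (CTMC) models
    of biochemical reaction networks. Provides a semi-analytic estimator
    that builds a rational approximation of the resolvent function G(s) by
    multipoint Pade interpolation, with Monte Carlo estimators of the Pade
    derivatives driven by exact stochastic simulation of an augmented chain
    carrying Erlang-lag shift registers; exact analytic PSDs and a PSD
    decomposition theorem for linear (affine-propensity) networks via the
    Lyapunov equation; a periodogram reference estimator; and a catalog of
    example networks (gene expression, RNA splicing, incoherent feedforward,
    negative feedback, repressilator, antithetic integral feedback,
    cell-cycle host with molecule partitioning).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
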