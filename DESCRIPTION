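Package: litmodel
Title: Leaky Integrating Threshold Models of Sensorimotor Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, reparameterization and fitting of the leaky
    integrating threshold (LIT) two-stage accumulator model of two-choice
    response times, in which a secondary leaky motor integrator re-integrates
    primary accumulated evidence and triggers the response at its own
    threshold. Provides Euler-Maruyama simulators for the LIT and the
    standard drift diffusion model, the colored-noise boundary-inflation
    mapping onto an effective diffusion model, a Crank-Nicolson grid solver
    for first-passage choice-RT densities with collapsing bounds,
    quantile-based Monte-Carlo likelihoods, a shift-invariant distribution
    fit criterion with prepaid-grid estimation, urgency-mechanism model
    comparison by differential evolution, model-predicted signal-RT
    correlation analyses, and a multivariate EEG pipeline (band-pass
    filtering, PCA blink removal, sliding-window linear discriminant
    decoding, forward-model topographies, motor-accumulator extraction from
    slope snapshots) together with a fully parameterized synthetic-data
    generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    data.table,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
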