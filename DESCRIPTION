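Package: exertraj
Title: Modelling Trajectories of Perceived Exertion During Incremental Exercise
Version: 0.1.0
Authors@R: person("Exertraj", "Maintainers", email = "maintainers@exertraj.org",
    role = c("aut", "cre"))
Description: Tools for modelling individual trajectories of Borg ratings of
    perceived exertion as a function of the fraction of maximal work capacity
    reached during incremental ergometer exercise. Provides four per-subject
    model families (power, delay, power-delay, quadratic-delay) fitted by
    profiled box-constrained least squares with multistart, small-sample model
    selection criteria (RMSE, AICc, BIC), Bayesian mixed-effects changepoint
    models with fixed or subject-varying delays estimated by a
    Gibbs-within-Metropolis sampler with Gelman-Rubin diagnostics and
    complete-likelihood DIC, functional clustering of trajectories via
    B-spline coefficients and Gaussian mixtures, and a synthetic-cohort
    generator with stored ground truth for validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
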