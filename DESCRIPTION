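Package: superstat
Title: Superstatistical Cognitive Models with Amortized Neural Bayesian Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and estimating superstatistical (dynamic,
    non-stationary) stochastic models of behavior: a low-level observation
    model (Poisson counts or the diffusion decision model) whose parameters
    evolve under a high-level transition model (Gaussian random walk, vector
    autoregression, Gaussian process, regime switching, or inter-trial
    variability). Estimation of the joint filtering posterior over
    time-varying and static parameters is performed either by exhaustive
    grid filtering (low-dimensional oracle) or by an amortized recurrent
    neural approximator trained purely on model simulations. Includes a
    model-criticism toolbox: simulation-based calibration, parameter
    recovery, retrodictive re-simulation, multi-horizon prediction, maximum
    mean discrepancy, and moving-average smoothing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
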