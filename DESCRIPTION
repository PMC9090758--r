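Package: accumdcm
Title: Evidence Accumulation and Effective Connectivity Modelling of
    Emotional Face Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage generative modelling of a dynamic face- and
    shape-matching experiment in adolescent depression. Stage one fits a
    hierarchical linear ballistic accumulator (LBA) model to choice
    response-time data with a Differential Evolution MCMC sampler,
    selects among condition-dependence variants by expected log pointwise
    predictive density (WAIC), compares groups via highest posterior
    density intervals, and runs posterior-predictive cohort simulations.
    Stage two models effective connectivity in a four-region
    prefrontal-amygdala network (FFA, LPFC, sgACC, amygdala) with a
    bilinear dynamic causal model and balloon-Windkessel hemodynamics,
    inverted by variational Laplace, followed by Parametric Empirical
    Bayes group inference with Bayesian model reduction/averaging and
    leave-one-out cross-validated diagnosis classification. A synthetic
    cohort generator reproduces the study design (33 controls, 30
    patients; 80 trials per subject; 335 volumes at TR 1.6 s) so the full
    pipeline runs without access to patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    pROC
Config/testthat/edition: 3
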