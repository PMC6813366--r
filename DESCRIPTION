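Package: RRPool
Title: Readily Releasable Vesicle Pool Size Estimation from EPSP Train Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the readily releasable vesicle pool size (N_RRP) per synaptic
    contact from trains of evoked postsynaptic potentials. Implements a stochastic
    multi-vesicular generalization of the Tsodyks-Markram short-term plasticity model,
    passive-membrane EPSP synthesis with Ornstein-Uhlenbeck membrane noise, voltage
    deconvolution and genetic-algorithm fitting of synaptic parameters, jackknife
    (leave-one-out) coefficient-of-variation profiles, and a CV-matching estimator that
    recovers the mean pool size of a cohort of connections by scanning shifted-Poisson
    pool-size distributions. Includes a synthetic-cohort generator with full ground
    truth for validating the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    data.table,
    fitdistrplus,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
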