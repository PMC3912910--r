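Package: fgmabc
Title: Fisher's Geometric Model Simulation and Approximate Bayesian
    Computation for Mutation Accumulation and Fitness Recovery Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates bacterial evolution on Fisher's geometric fitness
    landscape under two experimental demographies: a mutation-accumulation
    design with single-cell bottlenecks every 23 generations, and a fitness
    recovery design at large constant effective population size. Reduces
    simulated and observed experiments to a 39-statistic summary vector
    (binned mutation-accumulation fitness distributions plus fitness-recovery
    regression coefficients) and estimates the genomic rate of
    fitness-altering mutations U, the number of phenotypic traits n, and the
    mutational effect size sigma by rejection-sampling approximate Bayesian
    computation. Also provides competition-assay fitness arithmetic,
    distribution-of-fitness-effects utilities with a drift-survival filter,
    and estimator-performance diagnostics (parameter recovery and prediction
    error).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
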