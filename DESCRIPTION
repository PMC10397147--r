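Package: netsir
Title: Mean-Field SIR Models, Exact Pairwise Closure, and Survival-Based
    Inference on Configuration Model Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for SIR epidemics on configuration model networks.
    Represents degree distributions through probability generating
    functions, solves the closed pairwise, edge-based (Volz), and
    dynamical survival analysis (DSA) mean-field systems, and
    characterizes the Poisson-type degree distributions (Poisson,
    binomial, negative binomial) for which the pairwise triple closure
    is exact.  Includes an event-driven stochastic simulator for ground
    truth, the reduction of the DSA system to a single autonomous
    survival equation with final-size root solving, and maximum
    likelihood fitting of epidemic parameters from observed infection
    times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
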