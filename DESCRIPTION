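Package: redeval
Title: Evaluating Reductions of Biochemical ODE Models Under Parameter
    Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding how far a kinetic model of a biochemical
    reaction network can be reduced when its parameters are uncertain.
    Candidate reductions clamp non-essential reaction complexes at the
    steady state of the full model.  All candidate reductions are simulated
    across parameter sets drawn from a log-normal uncertainty model,
    compared pairwise with a symmetric time-averaged relative trajectory
    error, clustered by single linkage, and scored against the full model
    with a two-sample Kolmogorov-Smirnov statistic on dendrogram leaf
    positions.  The consistent reduction with the most clamped complexes is
    reported as the best reduced model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
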