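Package: orgbranch
Title: Minimal Biophysical Model of Branching Organoid Morphogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the growth of branched epithelial organoids
    as a balance between tip invasion, stochastic tip branching and a
    width-dependent proliferation feedback. Provides a deterministic
    mean-field growth model, a seeded stochastic spatial simulator of
    organoid trees with in-silico drug perturbations, morphometric
    measurement of simulated trees following standard branch-width and
    branch-counting conventions, regression-based recovery of the model
    parameters from morphometric tables, and a synthetic-data generator so
    the full simulate-measure-fit loop runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
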