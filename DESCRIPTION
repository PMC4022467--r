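Package: recirc
Title: Whole-Organism Kinetics of Lymphocyte Recirculation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental modelling of thoracic-duct lymphocyte (TDL)
    recirculation between blood, lung, liver, spleen, lymph nodes and
    Peyer's patches in the rat. Implements a linear ordinary-differential-
    equation model with gamma-distributed lymph-node transit times
    (sub-compartment chains), closed-form steady states, nonlinear
    least-squares and generalized-likelihood fitting of adoptive-transfer
    and thoracic-duct cannulation time courses, residual-bootstrap
    confidence intervals, F-test/AIC model comparison, and virtual
    experiments: steady-state perturbation scenarios (lung inflammation,
    blocked lymph-node entry or exit), cannulation output prediction,
    antigen-stimulated node decomposition and entry-blockade simulation.
    Includes a synthetic-data generator emulating the 51Cr-labelling
    experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
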