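Package: stochmi
Title: Time-Dependent Mutual Information in Stochastic Biochemical Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying information transmission through stochastic
    signaling cascades and gene-expression circuits. Builds chemical reaction
    networks with intrinsic noise and a slowly fluctuating global (extrinsic)
    variable coupled to translation rates, propagates their first two moments
    through a locally affine closure of the chemical master equation,
    reconstructs conditional output distributions as negative-binomial or
    normal laws, and computes time-dependent mutual information between step
    inputs and pathway readouts, including joint, conditional, and
    population-versus-single-cell decompositions. An exact Gillespie
    simulator serves as a validation oracle, and a synthetic flow-cytometry
    generator emulates per-cell reporter measurements for model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
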