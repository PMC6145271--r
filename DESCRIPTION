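Package: fermkin
Title: Unstructured Kinetic Modelling of Lactic Acid Bacteria Sausage
    Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Six-state unstructured kinetic model of lactic acid bacteria
    (LAB) growth during Thai fermented-sausage fermentation: Monod-logistic
    biomass growth with an exponential lag factor and cell lysis, coupled
    total-protein degradation and nonprotein-nitrogen release, and
    Luedeking-Piret rate laws for lactic acid, formic acid and glucose.
    The coupled system is solved by orthogonal collocation on finite
    elements (Gauss-Legendre nodes, compiled core) with an adaptive
    Runge-Kutta cross-check via 'deSolve'. Parameters are estimated by
    Metropolis-within-Gibbs Monte-Carlo sampling initialised from weighted
    least squares, validated by a per-state chi-squared goodness-of-fit
    test, and exercised end to end against a synthetic observation
    generator that emulates the duplicate-batch, triplicate-assay sampling
    design. A companion module computes sausage preparation plus transport
    costs for refrigerated and nonrefrigerated trucks, including piecewise
    driver-wage overtime rules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
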