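Package: stochid
Title: Practical Parameter Identifiability for Stochastic Biochemical
    Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for practical (sensitivity-based) parameter identifiability
    analysis of well-stirred chemical reaction networks modelled at three
    resolutions: the Chemical Master Equation (exact jump process), the
    Chemical Langevin Equation (diffusion approximation) and the deterministic
    reaction rate equations. Parametric sensitivities of the mean state are
    estimated by coupled finite-difference Monte Carlo schemes over exact
    stochastic simulations (common random numbers, common reaction paths, and
    the coupled finite-difference construction with split minimum/residual
    channels), by pathwise differentiation of the Langevin dynamics, or by
    forward sensitivity ODEs. From these, the package assembles concatenated
    non-dimensional sensitivity matrices and computes parameter-importance
    measures, collinearity indices, singular-value spectra and determinant
    measures, and selects identifiable parameter subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
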