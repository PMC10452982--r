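# tiny closed-form networks used across the suite

pure_birth <- function(c = 25) {
  reaction_network("S", matrix(1L, 1, 1),
                   list(propensity("zeroth", rate = "c")), c(c = c))
}

pure_death <- function(c = 2) {
  reaction_network("S", matrix(-1L, 1, 1),
                   list(propensity("first", "S", rate = "c")), c(c = c))
}

# infectious-disease network with the bilinear infection channel removed:
# all remaining reactions are of order <= 1, so the jump-process mean obeys
# the deterministic rate equations exactly
linear_epidemic <- function() {
  reaction_network(
    species = c("S1", "S2"),
    stoich = matrix(c(-1L, 0L, 0L, -1L, 1L, 0L, 0L, 1L), 2, 4),
    propensities = list(
      propensity("first", "S1", rate = "c1"),
      propensity("first", "S2", rate = "c2"),
      propensity("zeroth", rate = "c3"),
      propensity("zeroth", rate = "c4")),
    params = c(c1 = 2.0, c2 = 0.1, c3 = 25, c4 = 75))
}

# random unit-column matrix for collinearity property tests
random_unit_cols <- function(n, p) {
  m <- matrix(stats::rnorm(n * p), n, p)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

ensemble_var <- function(e) pmax(e$sumZ2 / e$R - (e$sumZ / e$R)^2, 0)
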