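#' Built-in case-study models
#'
#' Three small reaction networks used throughout the package's tests and
#' examples, each returned with its rate parameters, initial state and study
#' horizon.
#'
#' * `"infectious_disease"`: two species, `S1` (infected) and `S2`
#'   (susceptible), with death and birth channels for both and an infection
#'   channel `S1 + S2 -> S1 + S1`; `c = (2, 0.1, 25, 75, 0.05)`,
#'   `x0 = (20, 40)`, horizon 10.
#' * `"michaelis_menten"`: substrate `S1`, enzyme `S2`, complex `S3`,
#'   product `S4` with binding, unbinding and catalysis channels;
#'   `c1 = 1e6 / (nA * vol)` with `nA = 6.023e23` and `vol = 1e-15`
#'   (so `c1` is approximately `1.6604e-3`), `c2 = 1e-4`, `c3 = 0.1`.
#'   Initial counts are the rounded copy numbers of 5e-7 M substrate and
#'   2e-7 M enzyme in that volume: `x0 = (301, 120, 0, 0)`; horizon 50.
#' * `"toggle_switch"`: a bistable genetic switch in which each of two gene
#'   products `U`, `V` represses the synthesis of the other through a
#'   rational repression law; production propensities
#'   `alpha1 / (1 + XV^beta)` and `alpha2 / (1 + XU^gamma)`, unit-rate
#'   degradation of both species, `alpha1 = 50`, `beta = 2.5`,
#'   `alpha2 = 16`, `gamma = 1`, `x0 = (0, 0)`, horizon 50. The degradation
#'   channels carry fixed unit coefficients, so the identifiability analysis
#'   runs over the four named parameters rather than over reactions.
#'
#' @param name One of `"infectious_disease"`, `"michaelis_menten"`,
#'   `"toggle_switch"`.
#' @return A list with elements `network` ([reaction_network()]), `x0`
#'   (integer initial state) and `horizon` (end of the study interval).
#' @examples
#' m <- model_fixture("infectious_disease")
#' evaluate_propensities(m$network, m$x0)
#' @export
model_fixture <- function(name) {
  name <- match.arg(name, c("infectious_disease", "michaelis_menten",
                            "toggle_switch"))
  switch(name,
    infectious_disease = {
      net <- reaction_network(
        species = c("S1", "S2"),
        stoich = matrix(c(-1L, 0L,  0L, -1L,  1L, 0L,  0L, 1L,  1L, -1L), 2, 5),
        propensities = list(
          propensity("first", "S1", rate = "c1"),
          propensity("first", "S2", rate = "c2"),
          propensity("zeroth", rate = "c3"),
          propensity("zeroth", rate = "c4"),
          propensity("second_hetero", c("S1", "S2"), rate = "c5")),
        params = c(c1 = 2.0, c2 = 0.1, c3 = 25, c4 = 75, c5 = 0.05))
      list(network = net, x0 = c(S1 = 20, S2 = 40), horizon = 10)
    },
    michaelis_menten = {
      n_avogadro <- 6.023e23
      vol <- 1e-15
      net <- reaction_network(
        species = c("S1", "S2", "S3", "S4"),
        stoich = matrix(c(-1L, -1L, 1L, 0L,
                           1L,  1L, -1L, 0L,
                           0L,  1L, -1L, 1L), 4, 3),
        propensities = list(
          propensity("second_hetero", c("S1", "S2"), rate = "c1"),
          propensity("first", "S3", rate = "c2"),
          propensity("first", "S3", rate = "c3")),
        params = c(c1 = 1e6 / (n_avogadro * vol), c2 = 1e-4, c3 = 1e-1))
      # round-half-away-from-zero of concentration * nA * vol
      x0 <- c(S1 = floor(5e-7 * n_avogadro * vol + 0.5),
              S2 = floor(2e-7 * n_avogadro * vol + 0.5), S3 = 0, S4 = 0)
      list(network = net, x0 = x0, horizon = 50)
    },
    toggle_switch = {
      net <- reaction_network(
        species = c("U", "V"),
        stoich = matrix(c(1L, 0L,  -1L, 0L,  0L, 1L,  0L, -1L), 2, 4),
        propensities = list(
          propensity("rational_repression", rate = "alpha1",
                     exponent = "beta", regulator = "V"),
          propensity("first", "U"),
          propensity("rational_repression", rate = "alpha2",
                     exponent = "gamma", regulator = "U"),
          propensity("first", "V")),
        params = c(alpha1 = 50, beta = 2.5, alpha2 = 16, gamma = 1))
      list(network = net, x0 = c(U = 0, V = 0), horizon = 50)
    })
}
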