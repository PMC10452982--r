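test_that("mass-action and repression propensities evaluate correctly", {
  m <- model_fixture("infectious_disease")
  expect_equal(evaluate_propensities(m$network, m$x0), c(40, 4, 25, 75, 40))

  homo <- reaction_network("S", matrix(-2L, 1, 1),
                           list(propensity("second_homo", "S", rate = "c")),
                           c(c = 1))
  expect_equal(evaluate_propensities(homo, 2), 1) # c*x*(x-1)/2
  expect_equal(evaluate_propensities(homo, 1), 0)
  expect_equal(evaluate_propensities(homo, 0), 0)

  tg <- model_fixture("toggle_switch")
  expect_equal(evaluate_propensities(tg$network, c(0, 0)), c(50, 0, 16, 0))
  # repression at regulator = 1: x^q = 1 regardless of q
  expect_equal(evaluate_propensities(tg$network, c(1, 1))[1], 25)
})

test_that("propensities stay non-negative over random states, all fixtures", {
  set.seed(1)
  for (name in c("infectious_disease", "michaelis_menten", "toggle_switch")) {
    m <- model_fixture(name)
    N <- length(m$network$species)
    for (i in 1:200) {
      x <- rpois(N, lambda = sample(c(0, 1, 5, 50, 500), N, replace = TRUE))
      expect_true(all(evaluate_propensities(m$network, x) >= 0))
    }
  }
})

test_that("analytic propensity derivatives match central differences", {
  set.seed(2)
  h <- 1e-6
  for (name in c("infectious_disease", "michaelis_menten", "toggle_switch")) {
    m <- model_fixture(name)
    net <- m$network
    N <- length(net$species); P <- length(net$params)
    for (rep in 1:20) {
      x <- runif(N, 0.5, 50)
      dv <- propensity_derivatives(net, x)
      for (i in seq_len(N)) {
        xp <- x; xm <- x
        xp[i] <- x[i] * (1 + h); xm[i] <- x[i] * (1 - h)
        fd <- (evaluate_propensities(net, xp) -
                 evaluate_propensities(net, xm)) / (2 * h * x[i])
        expect_equal(dv$state[, i], fd, tolerance = 1e-6)
      }
      for (k in seq_len(P)) {
        pp <- net$params; pm <- net$params
        pp[k] <- pp[k] * (1 + h); pm[k] <- pm[k] * (1 - h)
        fd <- (evaluate_propensities(net, x, pp) -
                 evaluate_propensities(net, x, pm)) / (2 * h * net$params[k])
        expect_equal(unname(dv$params[, k]), fd, tolerance = 1e-6)
      }
    }
  }
})

test_that("repression derivatives vanish at a zero regulator", {
  tg <- model_fixture("toggle_switch")
  dv <- propensity_derivatives(tg$network, c(0, 0))
  expect_equal(unname(dv$state[1, "V"]), 0)       # d a1 / d XV at XV = 0
  expect_equal(unname(dv$params[1, "beta"]), 0)   # d a1 / d beta at XV = 0
  expect_equal(unname(dv$params[1, "alpha1"]), 1) # 1/(1 + 0)
})

test_that("first-order derivative forms are exact", {
  pd <- pure_death(c = 2)
  dv <- propensity_derivatives(pd, 7)
  expect_equal(unname(dv$state[1, 1]), 2)   # d(cx)/dx = c
  expect_equal(unname(dv$params[1, 1]), 7)  # d(cx)/dc = x
  homo <- reaction_network("S", matrix(-2L, 1, 1),
                           list(propensity("second_homo", "S", rate = "c")),
                           c(c = 2))
  expect_equal(unname(propensity_derivatives(homo, 3)$state[1, 1]), 5) # c(2x-1)/2
})

test_that("network construction rejects inconsistent inputs", {
  expect_error(reaction_network("S", matrix(1L, 1, 1), list(), c(c = 1)),
               "at least one reaction")
  expect_error(
    reaction_network("S", matrix(1L, 1, 1),
                     list(propensity("zeroth", rate = "nope")), c(c = 1)),
    "unknown parameter")
  expect_error(
    reaction_network("S", matrix(1L, 1, 1),
                     list(propensity("first", "X", rate = "c")), c(c = 1)),
    "unknown species")
  expect_error(
    reaction_network("S", matrix(1L, 1, 1),
                     list(propensity("zeroth", rate = "c")), c(c = -1)),
    "positive")
  expect_error(propensity("second_hetero", c("A", "A"), rate = "c"),
               "incompatible")
  expect_error(evaluate_propensities(pure_death(), -1), "non-negative")
})

test_that("model configs round-trip through YAML", {
  for (name in c("infectious_disease", "michaelis_menten", "toggle_switch")) {
    m <- model_fixture(name)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_model(m, path)
    m2 <- read_model(path)
    expect_equal(m2$network$species, m$network$species)
    expect_equal(m2$network$stoich, m$network$stoich)
    expect_equal(m2$network$params, m$network$params)
    expect_equal(unname(m2$x0), unname(as.numeric(m$x0)))
    expect_equal(m2$horizon, m$horizon)
    expect_equal(evaluate_propensities(m2$network, m$x0),
                 evaluate_propensities(m$network, m$x0))
  }
})

test_that("config parsing reports field paths on bad input", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("species: [S]", "reactions: []",
               "parameters: {c: 1}", "initial_state: {S: 0}", "horizon: 1"),
             path)
  expect_error(read_model(path), "at least one reaction")
  writeLines(c("species: [S]",
               "reactions:",
               "- reactants: []",
               "  products: [S]",
               "  propensity: {kind: warp, rate: c}",
               "parameters: {c: 1}", "initial_state: {S: 0}", "horizon: 1"),
             path)
  expect_error(read_model(path), "reactions\\[1\\].*kind")
  expect_error(read_model(tempfile()), "not found")
})

test_that("fixtures match their published parameterizations", {
  id <- model_fixture("infectious_disease")
  expect_equal(id$network$params,
               c(c1 = 2.0, c2 = 0.1, c3 = 25, c4 = 75, c5 = 0.05))
  expect_equal(id$horizon, 10)
  mm <- model_fixture("michaelis_menten")
  expect_equal(unname(mm$x0), c(301, 120, 0, 0))
  expect_equal(unname(mm$network$params["c1"]), 1e6 / (6.023e23 * 1e-15))
  expect_equal(unname(mm$network$params["c2"]), 1e-4)
  expect_equal(mm$horizon, 50)
  tg <- model_fixture("toggle_switch")
  expect_equal(unname(tg$x0), c(0, 0))
  expect_equal(tg$network$params,
               c(alpha1 = 50, beta = 2.5, alpha2 = 16, gamma = 1))
  expect_error(model_fixture("unknown_model"))
})

test_that("states stay non-negative when reactions fire only at positive rates", {
  set.seed(3)
  for (name in c("infectious_disease", "michaelis_menten", "toggle_switch")) {
    m <- model_fixture(name)
    net <- m$network
    x <- as.numeric(m$x0)
    for (step in 1:2000) {
      a <- evaluate_propensities(net, x)
      if (all(a <= 0)) break
      j <- sample(which(a > 0), 1)
      x <- x + net$stoich[, j]
      expect_true(all(x >= 0))
    }
  }
})
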