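test_that("SSA reproduces Poisson-process moments for a pure birth", {
  net <- pure_birth(25)
  g <- time_grid(1, 2)
  x <- vapply(1:2000, function(s) ssa_simulate(net, 0, g, seed = s)$states[2, 1],
              numeric(1))
  # X(1) ~ Poisson(25)
  expect_lt(abs(mean(x) - 25), 4 * sqrt(25 / 2000))
})

test_that("a pure death process is absorbed at zero by T = 10", {
  net <- pure_death(2)
  g <- time_grid(10, 3)
  x <- vapply(1:300, function(s) {
    tr <- ssa_simulate(net, 20, g, seed = s)
    tr$states[3, 1]
  }, numeric(1))
  expect_true(all(x == 0)) # E[X(10)] = 20 exp(-20), survival prob ~ 4e-8
})

test_that("simulators are deterministic given a seed", {
  m <- model_fixture("infectious_disease")
  g <- time_grid(10, 51)
  expect_identical(ssa_simulate(m$network, m$x0, g, seed = 7)$states,
                   ssa_simulate(m$network, m$x0, g, seed = 7)$states)
  expect_identical(rtc_simulate(m$network, m$x0, g, seed = 7)$states,
                   rtc_simulate(m$network, m$x0, g, seed = 7)$states)
  expect_identical(cle_simulate(m$network, m$x0, g, seed = 7)$states,
                   cle_simulate(m$network, m$x0, g, seed = 7)$states)
  expect_false(identical(ssa_simulate(m$network, m$x0, g, seed = 8)$states,
                         ssa_simulate(m$network, m$x0, g, seed = 7)$states))
})

test_that("random-time-change event counts are Poisson for a pure birth", {
  net <- pure_birth(25)
  g <- time_grid(1, 2)
  counts <- vapply(1:2000, function(s)
    rtc_simulate(net, 0, g, seed = s)$states[2, 1], numeric(1))
  # chi-square GOF against Poisson(25), binned tails
  br <- c(-Inf, 15, 18, 21, 24, 27, 30, 33, Inf)
  obs <- table(cut(counts, br))
  p <- diff(ppois(c(-Inf, 15, 18, 21, 24, 27, 30, 33, Inf), 25))
  expect_gt(chisq.test(as.vector(obs), p = p)$p.value, 0.01)
})

test_that("zero total propensity freezes the state", {
  net <- pure_death(2)
  tr <- rtc_simulate(net, 0, time_grid(5, 11), seed = 1)
  expect_true(all(tr$states == 0))
  expect_equal(tr$n_events, 0)
})

test_that("SSA and RTC agree in distribution on the epidemic model", {
  m <- model_fixture("infectious_disease")
  g <- time_grid(10, 2)
  a <- vapply(1:500, function(s)
    ssa_simulate(m$network, m$x0, g, seed = s)$states[2, 1], numeric(1))
  b <- vapply(1:500, function(s)
    rtc_simulate(m$network, m$x0, g, seed = 10000 + s)$states[2, 1], numeric(1))
  expect_gt(suppressWarnings(ks.test(a, b))$p.value, 0.01)
})

test_that("the event cap aborts runaway simulations loudly", {
  net <- pure_birth(1e4)
  expect_error(ssa_simulate(net, 0, time_grid(10, 3), seed = 1,
                            max_events = 100),
               "event cap")
})

test_that("Langevin paths have the right drift and degenerate limits", {
  # no reaction can fire from an empty state in a first-order network
  net <- pure_death(2)
  p <- cle_simulate(net, 0, time_grid(1, 11), dt = 1e-3, seed = 2)
  expect_true(all(p$states == 0))
  # pure birth mean: drift-only expectation 25 at t = 1
  nb <- pure_birth(25)
  xs <- vapply(1:500, function(s)
    cle_simulate(nb, 0, time_grid(1, 2), dt = 1e-3, seed = s)$states[2, 1],
    numeric(1))
  expect_lt(abs(mean(xs) - 25), 4 * sd(xs) / sqrt(500))
  expect_error(cle_simulate(nb, 0, time_grid(1, 2), dt = -1), "positive")
  expect_error(cle_simulate(nb, 0, time_grid(1, 101), dt = 0.5),
               "grid spacing")
})

test_that("substrate mass is conserved along Langevin paths of the enzyme model", {
  mm <- model_fixture("michaelis_menten")
  cons <- replicate(20, {
    p <- cle_simulate(mm$network, mm$x0, time_grid(50, 11), dt = 1e-3,
                      seed = sample.int(1e6, 1))
    p$states[, 1] + p$states[, 3] + p$states[, 4]
  })
  # zero clamping breaks exactness only marginally at these populations
  expect_lt(max(abs(cons - 301)), 301 * 0.01)
})

test_that("rate equations match closed forms and conservation laws", {
  nb <- pure_birth(25)
  g <- time_grid(1, 11)
  expect_equal(as.vector(rre_solve(nb, 0, g)), 25 * g, tolerance = 1e-8)

  mm <- model_fixture("michaelis_menten")
  X <- rre_solve(mm$network, mm$x0, time_grid(50, 26))
  expect_lt(max(abs(X[, 1] + X[, 3] + X[, 4] - 301)), 1e-6)
  expect_lt(max(abs(X[, 2] + X[, 3] - 120)), 1e-6)

  # deterministic toggle settles at a fixed point of the repression laws
  tg <- model_fixture("toggle_switch")
  X <- rre_solve(tg$network, tg$x0, time_grid(500, 11))
  u <- X[11, 1]; v <- X[11, 2]
  expect_lt(abs(u - 50 / (1 + v^2.5)), 1e-6)
  expect_lt(abs(v - 16 / (1 + u)), 1e-6)
})
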