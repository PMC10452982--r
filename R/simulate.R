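#' Uniform sampling grid over a study interval
#'
#' @param horizon End of the interval `[0, horizon]`.
#' @param length.out Number of grid points, including both endpoints. The
#'   default (501, i.e. 500 uniform steps) matches the resolution used by the
#'   bundled case-study reproductions.
#' @return Strictly increasing numeric vector starting at 0.
#' @export
time_grid <- function(horizon, length.out = 501L) {
  if (length.out < 2L) stop("a time grid needs at least 2 points", call. = FALSE)
  if (horizon <= 0) stop("'horizon' must be positive", call. = FALSE)
  seq(0, horizon, length.out = length.out)
}

check_grid <- function(grid) {
  if (length(grid) < 2L || grid[1] != 0 || any(diff(grid) <= 0)) {
    stop("'grid' must be strictly increasing and start at 0", call. = FALSE)
  }
  as.numeric(grid)
}

check_x0 <- function(net, x0) {
  x0 <- as.numeric(x0)
  if (length(x0) != length(net$species) || any(x0 < 0) || any(x0 != round(x0))) {
    stop("'x0' must give a non-negative integer count for every species",
         call. = FALSE)
  }
  x0
}

new_trajectory <- function(grid, states, n_events, seed, method) {
  colnames(states) <- NULL
  structure(list(grid = grid, states = states, n_events = n_events,
                 seed = seed, method = method),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$method, ", ", nrow(x$states), " grid points, ",
      format(x$n_events, big.mark = ","), " events (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Exact stochastic simulation of a reaction network
#'
#' `ssa_simulate()` runs Gillespie's direct method: each event draws a
#' waiting time `tau = -log(eta1)/a0` and picks the smallest reaction index
#' whose cumulative propensity exceeds `eta2 * a0`. `rtc_simulate()` runs the
#' random-time-change (modified next reaction) scheme, in which each reaction
#' carries its own unit-rate Poisson clock realized from a dedicated Exp(1)
#' stream; the two samplers are distributionally equivalent. Trajectories are
#' reported on `grid` by the last-event-before rule: the state at `t_l`
#' reflects every event with event time `<= t_l`. A state with zero total
#' propensity is absorbing. Identical `(seed, ...)` arguments reproduce the
#' trajectory bit for bit.
#'
#' @param net A [reaction_network()].
#' @param x0 Integer initial state.
#' @param grid Sampling grid from [time_grid()].
#' @param params Optional parameter override.
#' @param seed Integer seed for the simulation's random streams.
#' @param max_events Per-trajectory event cap; exceeding it is an error
#'   (guards against runaway models).
#' @return A `"trajectory"` object with fields `grid`, `states`
#'   (`L x N` integer matrix), `n_events`, `seed`.
#' @examples
#' m <- model_fixture("infectious_disease")
#' tr <- ssa_simulate(m$network, m$x0, time_grid(10, 101), seed = 1)
#' tr$states[101, ] # state at t = 10
#' @export
ssa_simulate <- function(net, x0, grid, params = NULL, seed = 1L,
                         max_events = 1e7) {
  cd <- net_codes(net, params)
  grid <- check_grid(grid)
  x0 <- check_x0(net, x0)
  res <- .cpp_ssa(cd$nu, cd$kind, cd$r1, cd$r2, cd$ratep, cd$expp, cd$reg,
                  cd$par, x0, grid, seed, 1, max_events)
  new_trajectory(grid, res$states, res$n_events, seed, "SSA")
}

#' @rdname ssa_simulate
#' @export
rtc_simulate <- function(net, x0, grid, params = NULL, seed = 1L,
                         max_events = 1e7) {
  cd <- net_codes(net, params)
  grid <- check_grid(grid)
  x0 <- check_x0(net, x0)
  res <- .cpp_rtc(cd$nu, cd$kind, cd$r1, cd$r2, cd$ratep, cd$expp, cd$reg,
                  cd$par, x0, grid, seed, 1, max_events)
  new_trajectory(grid, res$states, res$n_events, seed, "RTC")
}

#' Euler-Maruyama simulation of the chemical Langevin dynamics
#'
#' Integrates the diffusion approximation of the jump process, in which each
#' reaction contributes drift `nu_j a_j dt` and noise `nu_j sqrt(a_j) dW_j`.
#' Propensities are clamped at zero before the square root and the state is
#' clamped at zero after each step, which preserves the drift-dominated mean
#' at the population sizes the approximation is valid for.
#'
#' @inheritParams ssa_simulate
#' @param x0 Real-valued initial state (non-negative).
#' @param dt Euler-Maruyama step; must not exceed the smallest grid spacing.
#' @return A list with `grid`, `states` (`L x N` real matrix), `dt`, `seed`.
#' @export
cle_simulate <- function(net, x0, grid, dt = 1e-3, params = NULL, seed = 1L) {
  cd <- net_codes(net, params)
  grid <- check_grid(grid)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (dt > min(diff(grid)) + 1e-12) {
    stop("'dt' must not exceed the smallest grid spacing", call. = FALSE)
  }
  x0 <- as.numeric(x0)
  if (any(x0 < 0)) stop("'x0' must be non-negative", call. = FALSE)
  states <- .cpp_cle(cd$nu, cd$kind, cd$r1, cd$r2, cd$ratep, cd$expp, cd$reg,
                     cd$par, x0, grid, dt, seed, 1)
  structure(list(grid = grid, states = states, dt = dt, seed = seed,
                 method = "CLE"),
            class = "cle_path")
}

# propensity vector from the integer-coded representation (real-valued state)
prop_cd <- function(cd, x) {
  vapply(seq_along(cd$kind), function(j) {
    c_j <- if (cd$ratep[j] >= 0L) cd$par[cd$ratep[j] + 1L] else 1
    switch(cd$kind[j] + 1L,
      c_j,
      c_j * x[cd$r1[j] + 1L],
      c_j * x[cd$r1[j] + 1L] * x[cd$r2[j] + 1L],
      0.5 * c_j * x[cd$r1[j] + 1L] * (x[cd$r1[j] + 1L] - 1),
      {
        q <- cd$par[cd$expp[j] + 1L]
        xr <- x[cd$reg[j] + 1L]
        xq <- if (xr <= 0) (if (q == 0) 1 else 0) else xr^q
        c_j / (1 + xq)
      })
  }, numeric(1))
}

# propensity derivatives from the integer-coded representation:
# list(state = M x N, params = M x P)
derivs_cd <- function(cd, x) {
  M <- length(cd$kind); N <- nrow(cd$nu); P <- length(cd$par)
  dx <- matrix(0, M, N)
  dc <- matrix(0, M, P)
  for (j in seq_len(M)) {
    c_j <- if (cd$ratep[j] >= 0L) cd$par[cd$ratep[j] + 1L] else 1
    i1 <- cd$r1[j] + 1L; i2 <- cd$r2[j] + 1L; kp <- cd$ratep[j] + 1L
    switch(cd$kind[j] + 1L,
      { if (kp > 0) dc[j, kp] <- 1 },
      {
        dx[j, i1] <- c_j
        if (kp > 0) dc[j, kp] <- x[i1]
      },
      {
        dx[j, i1] <- c_j * x[i2]; dx[j, i2] <- c_j * x[i1]
        if (kp > 0) dc[j, kp] <- x[i1] * x[i2]
      },
      {
        dx[j, i1] <- 0.5 * c_j * (2 * x[i1] - 1)
        if (kp > 0) dc[j, kp] <- 0.5 * x[i1] * (x[i1] - 1)
      },
      {
        q <- cd$par[cd$expp[j] + 1L]
        ir <- cd$reg[j] + 1L; xr <- x[ir]
        xq <- if (xr <= 0) (if (q == 0) 1 else 0) else xr^q
        den <- (1 + xq)^2
        dx[j, ir] <- if (xr <= 0) 0 else -c_j * q * xr^(q - 1) / den
        if (kp > 0) dc[j, kp] <- 1 / (1 + xq)
        dc[j, cd$expp[j] + 1L] <- if (xr <= 0) 0 else -c_j * xq * log(xr) / den
      })
  }
  list(state = dx, params = dc)
}

# shared right-hand side of the reaction rate equations
rre_rhs <- function(cd) {
  nu <- cd$nu
  storage.mode(nu) <- "double"
  function(t, y, parms) {
    a <- prop_cd(cd, pmax(y, 0))
    list(as.vector(nu %*% a))
  }
}

#' Deterministic reaction-rate-equation solution
#'
#' Integrates `dX/dt = sum_j nu_j a_j(X, c)` with a stiff-capable solver
#' (lsoda). Conservation laws (left null space of the stoichiometric matrix)
#' are preserved to integrator tolerance.
#'
#' @inheritParams cle_simulate
#' @param rtol,atol Relative and absolute integrator tolerances. The tight
#'   defaults make table-level digits of downstream identifiability measures
#'   integrator-independent.
#' @return `L x N` matrix of the deterministic state on the grid.
#' @export
rre_solve <- function(net, x0, grid, params = NULL, rtol = 1e-8, atol = 1e-10) {
  cd <- net_codes(net, params)
  grid <- check_grid(grid)
  sol <- deSolve::ode(y = as.numeric(x0), times = grid, func = rre_rhs(cd),
                      parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("RRE integration failed; last successful time ",
         max(sol[, 1]), call. = FALSE)
  }
  out <- unname(sol[, -1, drop = FALSE])
  dimnames(out) <- list(NULL, net$species)
  out
}
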