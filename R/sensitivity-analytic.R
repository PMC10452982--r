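#' Forward sensitivity ODEs for the reaction rate equations
#'
#' Solves the coupled `(N + N*P)`-dimensional system of the deterministic
#' state and its parameter sensitivities,
#' \deqn{\frac{dS}{dt} = \sum_j \nu_j \Big( \frac{\partial a_j}{\partial c}
#'   + \frac{\partial a_j}{\partial X} S \Big),}
#' with initial conditions `X(0) = x0` and `S(0) = 0`.
#'
#' @inheritParams rre_solve
#' @return An `"rre_sensitivity"` object: `states` (`L x N`), `sens`
#'   (`L x N x P`), `means` (alias of `states`, the deterministic analogue
#'   of the mean trajectory), grid and metadata.
#' @examples
#' m <- model_fixture("michaelis_menten")
#' rs <- rre_sensitivity(m$network, m$x0, time_grid(50, 51))
#' rs$sens[51, "S4", "c3"] # d X_product(50) / d c3
#' @export
rre_sensitivity <- function(net, x0, grid, params = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  cd <- net_codes(net, params)
  grid <- check_grid(grid)
  N <- length(net$species); P <- length(cd$par)
  nu <- cd$nu
  storage.mode(nu) <- "double"
  rhs <- function(t, y, parms) {
    x <- pmax(y[seq_len(N)], 0)
    S <- matrix(y[-seq_len(N)], N, P)
    a <- prop_cd(cd, x)
    dv <- derivs_cd(cd, x)
    dS <- nu %*% (dv$params + dv$state %*% S)
    list(c(as.vector(nu %*% a), as.vector(dS)))
  }
  y0 <- c(as.numeric(x0), rep(0, N * P))
  sol <- deSolve::ode(y = y0, times = grid, func = rhs, parms = NULL,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("sensitivity ODE integration failed; last successful time ",
         max(sol[, 1]), call. = FALSE)
  }
  states <- unname(sol[, 1 + seq_len(N), drop = FALSE])
  sens <- array(sol[, -(1:(N + 1))], c(length(grid), N, P),
                dimnames = list(NULL, net$species, names(net$params)))
  dimnames(states) <- list(NULL, net$species)
  structure(
    list(grid = grid, species = net$species, param_names = names(net$params),
         states = states, means = states, sens = sens, stderr = NULL,
         backend = "RRE"),
    class = "rre_sensitivity")
}

#' @export
print.rre_sensitivity <- function(x, ...) {
  cat("<rre_sensitivity> deterministic forward sensitivities, ",
      length(x$grid), " grid points, parameters: ",
      paste(x$param_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pathwise sensitivities for the chemical Langevin dynamics
#'
#' Differentiating the Langevin system with respect to each rate parameter
#' gives a coupled SDE for `(X, dX/dc)`; both are integrated jointly by
#' Euler-Maruyama and averaged over `R` paths. The derivative of the
#' diffusion term carries the coefficient
#' `(da_j/dX . dX/dc + da_j/dc) / (2 sqrt(a_j))`, defined as 0 where
#' `a_j = 0` (the singularity is removable under the zero clamping of
#' [cle_simulate()]). Sensitivities start at zero at `t = 0`.
#'
#' @inheritParams cle_simulate
#' @param R Number of sample paths.
#' @return A `"cle_sensitivity"` object: `sens` (`L x N x P` ensemble-mean
#'   pathwise sensitivities), `stderr`, `means`/`means_stderr` (`L x N`),
#'   grid and metadata.
#' @export
cle_sensitivity <- function(net, x0, grid, dt = 1e-3, R = 10000L,
                            params = NULL, seed = 1L) {
  cd <- net_codes(net, params)
  grid <- check_grid(grid)
  if (dt <= 0 || dt > min(diff(grid)) + 1e-12) {
    stop("'dt' must be positive and no larger than the smallest grid spacing",
         call. = FALSE)
  }
  if (R < 2L) stop("'R' must be at least 2", call. = FALSE)
  x0 <- as.numeric(x0)
  res <- .cpp_cle_pathwise(cd$nu, cd$kind, cd$r1, cd$r2, cd$ratep, cd$expp,
                           cd$reg, cd$par, x0, grid, dt, as.integer(R), seed)
  L <- length(grid); N <- length(net$species); P <- length(cd$par)
  dn <- list(NULL, net$species, names(net$params))
  sens <- array(res$sumS / R, c(L, N, P), dimnames = dn)
  sens2 <- array(res$sumS2 / R, c(L, N, P))
  se <- sqrt(pmax(sens2 - sens^2, 0) / (R - 1))
  dimnames(se) <- dn
  means <- matrix(res$sumX / R, L, N, dimnames = list(NULL, net$species))
  m2 <- matrix(res$sumX2 / R, L, N)
  means_se <- sqrt(pmax(m2 - means^2, 0) / (R - 1))
  structure(
    list(grid = grid, species = net$species, param_names = names(net$params),
         sens = sens, stderr = se, means = means, means_stderr = means_se,
         R = as.integer(R), dt = dt, seed = seed, backend = "CLE"),
    class = "cle_sensitivity")
}

#' @export
print.cle_sensitivity <- function(x, ...) {
  cat("<cle_sensitivity> pathwise Langevin sensitivities, R=", x$R,
      " paths, dt=", format(x$dt), "\n", sep = "")
  invisible(x)
}
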