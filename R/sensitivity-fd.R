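#' Coupled perturbed/unperturbed trajectory pairs for one parameter
#'
#' Generates `R` coupled pairs of exact jump-process trajectories, one at the
#' nominal parameters `c` and one with slot `param` forward-perturbed to
#' `c_k + theta`, for finite-difference estimation of
#' `d E[X(t)] / d c_k`. Three couplings are available, in increasing order
#' of tightness (decreasing estimator variance):
#'
#' * `"CRN"` (common random numbers): both paths are independent Gillespie
#'   runs consuming the *same* uniform stream, each in its own per-event
#'   order (the paths desynchronize once their event counts differ).
#' * `"CRP"` (common reaction paths): both paths are random-time-change runs
#'   sharing the per-reaction Exp(1) streams, so reaction `j`'s `i`-th
#'   Poisson-clock increment is identical across the pair.
#' * `"CFD"` (coupled finite differences): a single joint jump process with
#'   three channels per reaction — a shared channel with rate
#'   `min(a_j, a_j')` firing both paths, and two residual channels with the
#'   leftover rates firing only one path each — simulated by the next
#'   reaction method with an independent Exp(1) stream per channel and all
#'   channel rates recomputed after every firing.
#'
#' At `theta = 0` all three couplings collapse to identical paths.
#'
#' @inheritParams ssa_simulate
#' @param param Parameter slot to perturb (name or index).
#' @param theta Perturbation size: a fraction of the parameter value when
#'   `mode = "relative"` (e.g. `0.05` for 5%), an absolute value otherwise.
#' @param mode `"relative"` or `"absolute"`.
#' @param R Number of coupled pairs.
#' @param estimator `"CFD"`, `"CRP"` or `"CRN"`.
#' @param keep_paths Keep the sampled pair trajectories (memory `2*L*N*R`
#'   integers) in addition to the accumulated moments.
#' @return A `"coupled_ensemble"` object carrying the grid, per-cell sums of
#'   the pathwise difference quotients `Z = (X' - X)/theta` and of the
#'   unperturbed paths, the absolute perturbation used, and metadata.
#' @seealso [fd_sensitivity()] for the full sensitivity tensor over all
#'   parameters.
#' @export
coupled_pairs <- function(net, x0, grid, param, theta, mode = c("relative", "absolute"),
                          R = 10000L, estimator = c("CFD", "CRP", "CRN"),
                          params = NULL, seed = 1L, max_events = 1e7,
                          keep_paths = FALSE) {
  estimator <- match.arg(estimator)
  mode <- match.arg(mode)
  cd <- net_codes(net, params)
  grid <- check_grid(grid)
  x0 <- check_x0(net, x0)
  if (R < 1L) stop("'R' must be at least 1", call. = FALSE)
  if (theta <= 0) stop("'theta' must be positive", call. = FALSE)
  k <- if (is.character(param)) match(param, names(net$params)) else as.integer(param)
  if (is.na(k) || k < 1L || k > length(net$params)) {
    stop("unknown parameter: ", param, call. = FALSE)
  }
  theta_abs <- if (mode == "relative") theta * cd$par[k] else theta
  fn <- switch(estimator, CFD = .cpp_cfd_ensemble, CRP = .cpp_crp_ensemble,
               CRN = .cpp_crn_ensemble)
  res <- fn(cd$nu, cd$kind, cd$r1, cd$r2, cd$ratep, cd$expp, cd$reg, cd$par,
            x0, grid, k - 1L, theta_abs, as.integer(R), seed, max_events,
            keep_paths)
  L <- length(grid); N <- length(net$species)
  out <- list(
    grid = grid, species = net$species,
    param = names(net$params)[k], param_index = k, theta = theta_abs,
    estimator = estimator, R = as.integer(R), seed = seed,
    sumZ = matrix(res$sumZ, L, N), sumZ2 = matrix(res$sumZ2, L, N),
    sumX = matrix(res$sumX, L, N), sumX2 = matrix(res$sumX2, L, N),
    n_events = res$n_events)
  if (keep_paths) {
    out$paths_unperturbed <- array(res$paths_unperturbed, c(L, N, R))
    out$paths_perturbed <- array(res$paths_perturbed, c(L, N, R))
  }
  structure(out, class = "coupled_ensemble")
}

#' @export
print.coupled_ensemble <- function(x, ...) {
  cat("<coupled_ensemble> ", x$estimator, ", parameter ", x$param,
      " (theta=", format(x$theta), "), R=", x$R, " pairs\n", sep = "")
  invisible(x)
}

#' Finite-difference sensitivity of the mean state
#'
#' Estimates the sensitivity tensor `S(t_l) = d E[X(t_l)] / d c` of the jump
#' process by forward finite differences over coupled trajectory pairs, one
#' ensemble per parameter slot (see [coupled_pairs()]). Each cell's estimate
#' is the ensemble mean of the pathwise quotient
#' `Z[r](t) = (X[r](t, c_k + theta) - X[r](t, c_k)) / theta` with Monte
#' Carlo standard error `sd(Z)/sqrt(R)`. The mean trajectory `E[X]` is
#' estimated from the unperturbed members of *all* parameter ensembles
#' pooled, since they are i.i.d. realizations at the nominal parameters.
#'
#' @inheritParams coupled_pairs
#' @param theta Perturbation (scalar, or one value per parameter).
#' @param ensembles Optionally, a pre-built list of [coupled_pairs()]
#'   ensembles, one per parameter slot, sharing grid, model and `R` (other
#'   generation arguments are then ignored).
#' @return A `"fd_sensitivity"` object: `sens` (`L x N x P` array), `stderr`
#'   (matching Monte Carlo standard errors), `means`/`means_stderr`
#'   (`L x N`), grid and metadata.
#' @examples
#' m <- model_fixture("michaelis_menten")
#' fit <- fd_sensitivity(m$network, m$x0, time_grid(50, 26), theta = 0.01,
#'                       R = 200, estimator = "CFD", seed = 7)
#' dim(fit$sens)
#' @export
fd_sensitivity <- function(net, x0, grid, theta, mode = c("relative", "absolute"),
                           R = 10000L, estimator = c("CFD", "CRP", "CRN"),
                           params = NULL, seed = 1L, max_events = 1e7,
                           ensembles = NULL) {
  estimator <- match.arg(estimator)
  mode <- match.arg(mode)
  if (is.null(ensembles)) {
    P <- length(net$params)
    theta <- rep_len(theta, P)
    # the same seed (hence the same underlying streams, pair for pair) is
    # used for every parameter's ensemble: common random numbers across the
    # parameter axis, which correlates the Monte Carlo noise of the columns
    # and stabilizes the collinearity indices computed from them
    ensembles <- lapply(seq_len(P), function(k) {
      coupled_pairs(net, x0, grid, param = k, theta = theta[k], mode = mode,
                    R = R, estimator = estimator, params = params,
                    seed = seed, max_events = max_events)
    })
  } else {
    grids <- vapply(ensembles, function(e) length(e$grid), integer(1))
    Rs <- vapply(ensembles, function(e) e$R, integer(1))
    if (length(unique(grids)) != 1L || length(unique(Rs)) != 1L) {
      stop("all ensembles must share the same grid and R", call. = FALSE)
    }
    R <- Rs[1]
    estimator <- ensembles[[1]]$estimator
  }
  if (R < 2L) {
    stop("R must be at least 2 for the standard error to be defined",
         call. = FALSE)
  }
  grid <- ensembles[[1]]$grid
  species <- ensembles[[1]]$species
  L <- length(grid); N <- length(species); P <- length(ensembles)
  pnames <- vapply(ensembles, function(e) e$param, character(1))
  sens <- se <- array(0, c(L, N, P), dimnames = list(NULL, species, pnames))
  sumX <- sumX2 <- matrix(0, L, N)
  for (k in seq_len(P)) {
    e <- ensembles[[k]]
    zbar <- e$sumZ / R
    sens[, , k] <- zbar
    se[, , k] <- sqrt(pmax(e$sumZ2 / R - zbar^2, 0) / (R - 1))
    sumX <- sumX + e$sumX
    sumX2 <- sumX2 + e$sumX2
  }
  n_pool <- R * P
  means <- sumX / n_pool
  means_se <- sqrt(pmax(sumX2 / n_pool - means^2, 0) / (n_pool - 1))
  dimnames(means) <- dimnames(means_se) <- list(NULL, species)
  structure(
    list(grid = grid, species = species, param_names = pnames,
         sens = sens, stderr = se, means = means, means_stderr = means_se,
         R = R, estimator = estimator,
         theta = vapply(ensembles, function(e) e$theta, numeric(1)),
         seed = ensembles[[1]]$seed, backend = estimator),
    class = "fd_sensitivity")
}

#' @export
print.fd_sensitivity <- function(x, ...) {
  cat("<fd_sensitivity> ", x$estimator, " estimator, R=", x$R,
      " pairs per parameter, ", length(x$grid), " grid points\n", sep = "")
  cat("  parameters: ", paste(x$param_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export a sensitivity estimate as a long-format data frame
#'
#' @param x A sensitivity object (`fd_sensitivity`, `cle_sensitivity` or
#'   `rre_sensitivity`).
#' @return Data frame with columns `time`, `species`, `parameter`,
#'   `estimate` and (for Monte Carlo backends) `stderr`, plus a `backend`
#'   column.
#' @export
sensitivity_long <- function(x) {
  L <- length(x$grid); N <- length(x$species); P <- length(x$param_names)
  out <- data.frame(
    time = rep(x$grid, times = N * P),
    species = rep(rep(x$species, each = L), times = P),
    parameter = rep(x$param_names, each = L * N),
    estimate = as.vector(x$sens),
    stringsAsFactors = FALSE)
  if (!is.null(x$stderr)) out$stderr <- as.vector(x$stderr)
  out$backend <- x$backend
  out
}
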