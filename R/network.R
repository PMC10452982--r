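#' Propensity descriptor for a single reaction channel
#'
#' Describes the kinetic law of one reaction. Five forms are supported:
#' * `"zeroth"`: constant rate, \eqn{a(x) = c}.
#' * `"first"`: \eqn{a(x) = c\, x_m} for a single reactant species \eqn{S_m}.
#' * `"second_hetero"`: \eqn{a(x) = c\, x_m x_n} for two distinct reactants.
#' * `"second_homo"`: \eqn{a(x) = \tfrac{1}{2} c\, x_m (x_m - 1)} for a
#'   dimerization \eqn{S_m + S_m \rightarrow}.
#' * `"rational_repression"`: \eqn{a(x) = p / (1 + x_{\mathrm{reg}}^{\,q})},
#'   the repressive Hill-type production law of gene-switch models, with
#'   production strength `rate` (\eqn{p}) and cooperativity exponent
#'   `exponent` (\eqn{q}) acting through the `regulator` species. The
#'   boundary conventions are \eqn{x^q \to 0} as \eqn{x \to 0^+} for
#'   \eqn{q > 0}, and \eqn{0^0 = 1}.
#'
#' @param kind One of `"zeroth"`, `"first"`, `"second_hetero"`,
#'   `"second_homo"`, `"rational_repression"`.
#' @param reactants Character vector of reactant species names (empty for
#'   `"zeroth"` and `"rational_repression"`; one name for `"first"` and
#'   `"second_homo"`; two distinct names for `"second_hetero"`).
#' @param rate Name of the rate-parameter slot, or `NULL` for a fixed unit
#'   coefficient (a reaction whose rate constant is not treated as a model
#'   parameter).
#' @param exponent Name of the exponent-parameter slot
#'   (`"rational_repression"` only).
#' @param regulator Name of the regulating species
#'   (`"rational_repression"` only).
#' @return An object of class `"propensity"`.
#' @seealso [reaction_network()]
#' @export
propensity <- function(kind, reactants = character(), rate = NULL,
                       exponent = NULL, regulator = NULL) {
  kind <- match.arg(kind, c("zeroth", "first", "second_hetero", "second_homo",
                            "rational_repression"))
  n_react <- length(reactants)
  ok <- switch(kind,
    zeroth = n_react == 0L,
    first = n_react == 1L,
    second_hetero = n_react == 2L && reactants[1] != reactants[2],
    second_homo = n_react == 1L,
    rational_repression = n_react == 0L)
  if (!ok) {
    stop("propensity kind '", kind, "' is incompatible with ", n_react,
         " reactant(s)", call. = FALSE)
  }
  if (kind == "rational_repression") {
    if (is.null(rate) || is.null(exponent) || is.null(regulator)) {
      stop("rational_repression requires 'rate', 'exponent' and 'regulator'",
           call. = FALSE)
    }
  }
  structure(
    list(kind = kind, reactants = as.character(reactants),
         rate = rate, exponent = exponent, regulator = regulator),
    class = "propensity")
}

#' Construct a well-stirred reaction network
#'
#' A reaction network couples `N` species through `M` reaction channels. Each
#' channel `j` carries a state-change (stoichiometric) vector, the `j`-th
#' column of `stoich`, and a [propensity()] descriptor giving its kinetic
#' law. Rate parameters live in named slots: most mass-action channels
#' reference exactly one slot, but a channel may reference none (fixed unit
#' coefficient) or, for the repression form, two (production strength and
#' cooperativity exponent), so the number of parameters need not equal the
#' number of reactions.
#'
#' @param species Character vector of `N` species names.
#' @param stoich Integer `N x M` matrix; column `j` is the state change of
#'   reaction `j`.
#' @param propensities List of `M` [propensity()] descriptors.
#' @param params Named numeric vector of positive rate-parameter values.
#' @return An object of class `"reaction_network"`.
#' @examples
#' # birth-death process: 0 -> S (rate b), S -> 0 (rate d)
#' net <- reaction_network(
#'   species = "S",
#'   stoich = matrix(c(1L, -1L), 1, 2),
#'   propensities = list(propensity("zeroth", rate = "b"),
#'                       propensity("first", "S", rate = "d")),
#'   params = c(b = 25, d = 2))
#' evaluate_propensities(net, 10)
#' @export
reaction_network <- function(species, stoich, propensities, params) {
  species <- as.character(species)
  stoich <- as.matrix(stoich)
  storage.mode(stoich) <- "integer"
  if (length(propensities) == 0L) {
    stop("a reaction network needs at least one reaction", call. = FALSE)
  }
  if (ncol(stoich) != length(propensities)) {
    stop("stoichiometric matrix has ", ncol(stoich), " columns but ",
         length(propensities), " propensity descriptors were given",
         call. = FALSE)
  }
  if (nrow(stoich) != length(species)) {
    stop("stoichiometric matrix has ", nrow(stoich), " rows but ",
         length(species), " species were given", call. = FALSE)
  }
  if (is.null(names(params)) || any(names(params) == "")) {
    stop("'params' must be a fully named numeric vector", call. = FALSE)
  }
  if (any(!is.finite(params)) || any(params <= 0)) {
    stop("all parameter values must be positive and finite", call. = FALSE)
  }
  net <- structure(
    list(species = species, stoich = stoich,
         propensities = lapply(propensities, identity),
         params = params),
    class = "reaction_network")
  # resolve and validate all name references once
  invisible(net_codes(net))
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species), " species, ",
      ncol(x$stoich), " reactions, ", length(x$params), " parameters\n",
      sep = "")
  cat("  species:   ", paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  parameters:",
      paste(sprintf("%s=%g", names(x$params), x$params), collapse = ", "),
      "\n")
  invisible(x)
}

kind_code <- c(zeroth = 0L, first = 1L, second_hetero = 2L,
               second_homo = 3L, rational_repression = 4L)

# Integer-coded network representation shared by the simulation backends
# (0-based indices; -1 marks an unused reference). Errors carry the field
# path of the offending descriptor.
net_codes <- function(net, params = NULL) {
  if (is.null(params)) params <- net$params
  if (!identical(sort(names(params)), sort(names(net$params)))) {
    stop("parameter names do not match the network's parameter slots",
         call. = FALSE)
  }
  params <- params[names(net$params)]
  M <- ncol(net$stoich)
  sp_idx <- function(nm, where) {
    i <- match(nm, net$species)
    if (anyNA(i)) {
      stop("unknown species '", nm[is.na(i)][1], "' in ", where, call. = FALSE)
    }
    i - 1L
  }
  par_idx <- function(nm, where) {
    if (is.null(nm)) return(-1L)
    i <- match(nm, names(net$params))
    if (is.na(i)) stop("unknown parameter '", nm, "' in ", where, call. = FALSE)
    i - 1L
  }
  kind <- r1 <- r2 <- ratep <- expp <- reg <- integer(M)
  for (j in seq_len(M)) {
    pr <- net$propensities[[j]]
    where <- paste0("reactions[", j, "].propensity")
    kind[j] <- kind_code[[pr$kind]]
    ri <- if (length(pr$reactants)) sp_idx(pr$reactants, where) else integer()
    r1[j] <- if (length(ri) >= 1L) ri[1] else -1L
    r2[j] <- if (length(ri) >= 2L) ri[2] else -1L
    ratep[j] <- par_idx(pr$rate, where)
    expp[j] <- par_idx(pr$exponent, where)
    reg[j] <- if (is.null(pr$regulator)) -1L else sp_idx(pr$regulator, where)
  }
  list(nu = net$stoich, kind = kind, r1 = r1, r2 = r2, ratep = ratep,
       expp = expp, reg = reg, par = unname(as.numeric(params)))
}

#' Evaluate all reaction propensities at a state
#'
#' @param net A [reaction_network()].
#' @param x Numeric state vector (molecule counts), length `N`.
#' @param params Optional named parameter vector overriding the network's
#'   values.
#' @return Numeric vector of `M` non-negative reaction rates.
#' @export
evaluate_propensities <- function(net, x, params = NULL) {
  cd <- net_codes(net, params)
  x <- as.numeric(x)
  if (length(x) != length(net$species)) {
    stop("state has length ", length(x), ", expected ", length(net$species),
         call. = FALSE)
  }
  if (any(x < 0)) stop("state entries must be non-negative", call. = FALSE)
  pmax(prop_cd(cd, x), 0)
}

#' Analytic derivatives of the propensity vector
#'
#' Returns the Jacobian of the propensity vector with respect to the
#' (real-valued) state and its gradient with respect to the rate parameters,
#' for use by the deterministic and diffusion sensitivity backends. For the
#' repression form the exponent derivative is
#' \eqn{\partial a / \partial q = -p\, x^q \ln x / (1 + x^q)^2}, with the
#' convention that it vanishes as \eqn{x \to 0^+}.
#'
#' @inheritParams evaluate_propensities
#' @return List with `state` (`M x N` Jacobian) and `params` (`M x P`
#'   gradient).
#' @export
propensity_derivatives <- function(net, x, params = NULL) {
  cd <- net_codes(net, params)
  x <- as.numeric(x)
  if (length(x) != length(net$species)) {
    stop("state has length ", length(x), ", expected ", length(net$species),
         call. = FALSE)
  }
  if (any(x < 0)) stop("state entries must be non-negative", call. = FALSE)
  out <- derivs_cd(cd, x)
  dimnames(out$state) <- list(NULL, net$species)
  dimnames(out$params) <- list(NULL, names(net$params))
  out
}

# conservation laws: columns span {w : w' nu = 0}, the left null space of the
# stoichiometric matrix
left_null_space <- function(stoich) {
  a <- t(stoich) # M x N
  s <- svd(a, nv = ncol(a))
  tol <- max(dim(a)) * max(s$d, 0) * .Machine$double.eps
  r <- sum(s$d > tol)
  if (r >= ncol(a)) return(matrix(0, nrow(stoich), 0))
  s$v[, seq(r + 1, ncol(a)), drop = FALSE]
}
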