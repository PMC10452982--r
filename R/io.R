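#' Read or write a model configuration file
#'
#' Models are stored as YAML (or JSON, which YAML subsumes) with keys
#' `species`, `reactions`, `parameters`, `initial_state` and `horizon`. Each
#' reaction lists its `reactants` and `products` (species names, repeated for
#' multiplicity) and a `propensity` block with a `kind` and the parameter
#' references the kind needs (`rate`, and for the repression form `exponent`
#' and `regulator`). Writing a model and reloading it yields an identical
#' model.
#'
#' @param path Path to a YAML/JSON model file.
#' @return `read_model()`: a list with `network`, `x0`, `horizon`, as for
#'   [model_fixture()].
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_model(model_fixture("michaelis_menten"), path)
#' m <- read_model(path)
#' m$network
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (key in c("species", "reactions", "parameters", "initial_state",
                "horizon")) {
    if (is.null(cfg[[key]])) {
      stop("model config is missing required key '", key, "'", call. = FALSE)
    }
  }
  species <- as.character(unlist(cfg$species))
  if (length(cfg$reactions) == 0L) {
    stop("reactions: model must declare at least one reaction", call. = FALSE)
  }
  params <- unlist(cfg$parameters)
  if (any(!is.finite(params)) || any(params <= 0)) {
    stop("parameters: all values must be positive and finite", call. = FALSE)
  }
  M <- length(cfg$reactions)
  stoich <- matrix(0L, length(species), M)
  props <- vector("list", M)
  for (j in seq_len(M)) {
    rx <- cfg$reactions[[j]]
    where <- paste0("reactions[", j, "]")
    count <- function(side) {
      nm <- as.character(unlist(rx[[side]]))
      idx <- match(nm, species)
      if (anyNA(idx)) {
        stop(where, ".", side, ": unknown species '", nm[is.na(idx)][1], "'",
             call. = FALSE)
      }
      tabulate(idx, nbins = length(species))
    }
    stoich[, j] <- count("products") - count("reactants")
    pb <- rx$propensity
    if (is.null(pb$kind) || !pb$kind %in% names(kind_code)) {
      stop(where, ".propensity.kind: unknown propensity kind '", pb$kind, "'",
           call. = FALSE)
    }
    props[[j]] <- propensity(
      kind = pb$kind,
      reactants = if (pb$kind %in% c("zeroth", "rational_repression"))
        character() else as.character(unlist(rx$reactants)),
      rate = pb$rate, exponent = pb$exponent, regulator = pb$regulator)
  }
  net <- reaction_network(species, stoich, props, params)
  x0 <- unlist(cfg$initial_state)[species]
  if (anyNA(x0) || any(x0 < 0) || any(x0 != round(x0))) {
    stop("initial_state: every species needs a non-negative integer count",
         call. = FALSE)
  }
  list(network = net, x0 = x0, horizon = as.numeric(cfg$horizon))
}

#' @rdname read_model
#' @param model A list with `network`, `x0`, `horizon` (as returned by
#'   [read_model()] or [model_fixture()]).
#' @export
write_model <- function(model, path) {
  net <- model$network
  species <- net$species
  reactions <- lapply(seq_along(net$propensities), function(j) {
    pr <- net$propensities[[j]]
    dv <- net$stoich[, j]
    # kinetic reactants come from the descriptor so that catalytic channels
    # (reactant also a product) round-trip; products follow from stoichiometry
    reac_counts <- if (length(pr$reactants)) {
      cnt <- tabulate(match(pr$reactants, species), nbins = length(species))
      if (pr$kind == "second_homo") cnt <- 2L * cnt
      cnt
    } else {
      pmax(-dv, 0)
    }
    reac <- rep(species, reac_counts)
    prod <- rep(species, reac_counts + dv)
    pb <- list(kind = pr$kind)
    if (!is.null(pr$rate)) pb$rate <- pr$rate
    if (!is.null(pr$exponent)) pb$exponent <- pr$exponent
    if (!is.null(pr$regulator)) pb$regulator <- pr$regulator
    list(reactants = as.list(reac), products = as.list(prod), propensity = pb)
  })
  cfg <- list(
    species = as.list(species),
    reactions = reactions,
    parameters = as.list(net$params),
    initial_state = as.list(stats::setNames(as.integer(model$x0), species)),
    horizon = model$horizon)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
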