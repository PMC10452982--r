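#' Run the full identifiability pipeline on a model
#'
#' Drives the whole workflow: simulate or solve the model with the chosen
#' sensitivity backend, assemble the concatenated non-dimensional
#' sensitivity matrix on a uniform grid, and compute importance measures,
#' collinearity indices, the singular spectrum and the identifiable-subset
#' report. Deterministic given `(arguments, seed)`.
#'
#' @param model A fixture name (see [model_fixture()]), a path to a model
#'   config file (see [read_model()]), or a list with `network`, `x0`,
#'   `horizon`.
#' @param backend `"RRE"` (forward sensitivity ODEs), `"CLE"` (pathwise
#'   Langevin sensitivities) or one of the jump-process finite-difference
#'   estimators `"CFD"`, `"CRP"`, `"CRN"`.
#' @param grid_length Number of grid points including both endpoints.
#' @param R Trajectory-pair (or path) count for the Monte Carlo backends.
#' @param theta Forward perturbation for the finite-difference backends.
#' @param mode `"relative"` (theta as a fraction of each parameter) or
#'   `"absolute"`.
#' @param dt Euler-Maruyama step for the CLE backend.
#' @param delta_threshold,ci_threshold,max_subset_size See
#'   [select_identifiable_subsets()].
#' @param mask_tol See [concat_sensitivity()].
#' @param seed Integer seed (Monte Carlo backends).
#' @param out_dir Optional directory; when given, the delta / collinearity /
#'   singular-value tables are written as CSV, the full report as JSON, and
#'   a run manifest records every argument and the seed.
#' @return An `"identifiability_report"` (see
#'   [select_identifiable_subsets()]) augmented with the backend, the
#'   concatenated matrix and the sensitivity object.
#' @examples
#' rep <- run_pipeline("michaelis_menten", backend = "RRE", grid_length = 51)
#' rep$subsets
#' @export
run_pipeline <- function(model, backend = c("RRE", "CFD", "CRP", "CRN", "CLE"),
                         grid_length = 501L, R = 10000L, theta = 0.05,
                         mode = c("relative", "absolute"), dt = 1e-3,
                         delta_threshold = 0.2, ci_threshold = 20,
                         max_subset_size = NULL, mask_tol = NULL,
                         seed = 1L, out_dir = NULL) {
  backend <- match.arg(backend)
  mode <- match.arg(mode)
  if (is.character(model)) {
    model <- if (file.exists(model)) read_model(model) else model_fixture(model)
  }
  net <- model$network
  grid <- time_grid(model$horizon, grid_length)
  sens <- switch(backend,
    RRE = rre_sensitivity(net, model$x0, grid),
    CLE = cle_sensitivity(net, model$x0, grid, dt = dt, R = R, seed = seed),
    fd_sensitivity(net, model$x0, grid, theta = theta, mode = mode, R = R,
                   estimator = backend, seed = seed))
  cs <- concat_sensitivity(sens, params = net$params, mask_tol = mask_tol)
  dl <- delta_msqr(cs)
  ns <- normalize_columns(cs)
  report <- select_identifiable_subsets(ns, dl,
                                        delta_threshold = delta_threshold,
                                        ci_threshold = ci_threshold,
                                        max_subset_size = max_subset_size)
  report$backend <- backend
  # report the spectrum of the raw non-dimensional matrix (the scale on
  # which the case studies print it); keep the unit-column spectrum too
  sp <- svd_spectrum(cs)
  report$singular_values_normalized <- report$singular_values
  report$singular_values <- sp$values
  report$rank <- sp$rank
  report$concat <- cs
  report$normalized <- ns
  report$sensitivity <- sens
  report$seed <- seed
  if (!is.null(out_dir)) {
    write_report(report, out_dir,
                 manifest = list(backend = backend, grid_length = grid_length,
                                 R = R, theta = theta, mode = mode, dt = dt,
                                 delta_threshold = delta_threshold,
                                 ci_threshold = ci_threshold,
                                 seed = seed))
  }
  report
}

#' Write an identifiability report to disk
#'
#' Writes `delta.csv`, one `collinearity_k<size>.csv` per subset size,
#' `svd.csv`, the full report as `report.json` and a `manifest.json`
#' recording the run configuration.
#'
#' @param report An `"identifiability_report"` from [run_pipeline()] or
#'   [select_identifiable_subsets()].
#' @param dir Output directory (created if needed).
#' @param manifest Optional named list of run metadata to store alongside.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, manifest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(dir, recursive = TRUE), add = TRUE)
  utils::write.csv(
    data.frame(parameter = names(report$delta), delta_msqr = report$delta),
    file.path(dir, "delta.csv"), row.names = FALSE)
  if (nrow(report$subsets)) {
    for (k in unique(report$subsets$size)) {
      utils::write.csv(report$subsets[report$subsets$size == k, ],
                       file.path(dir, sprintf("collinearity_k%d.csv", k)),
                       row.names = FALSE)
    }
  }
  utils::write.csv(
    data.frame(index = seq_along(report$singular_values),
               singular_value = report$singular_values),
    file.path(dir, "svd.csv"), row.names = FALSE)
  core <- list(
    backend = report$backend, delta = as.list(report$delta),
    ranked_params = report$ranked_params, subsets = report$subsets,
    singular_values = report$singular_values, rank = report$rank,
    thresholds = report$thresholds, seed = report$seed)
  jsonlite::write_json(core, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(manifest)) {
    manifest$package_version <- as.character(utils::packageVersion("stochid"))
    manifest$r_version <- R.version.string
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  ok <- TRUE
  invisible(dir)
}

#' Compare identifiability results across sensitivity backends
#'
#' Runs [run_pipeline()] once per backend on the same model, grid and
#' thresholds and merges the per-subset collinearity indices and
#' per-parameter importance measures into side-by-side tables.
#'
#' @inheritParams run_pipeline
#' @param backends Character vector of backends to compare.
#' @param ... Further arguments passed to [run_pipeline()].
#' @return List with `delta` (one column per backend), `collinearity`
#'   (subset rows, one CI column per backend) and `reports` (the individual
#'   reports).
#' @export
compare_backends <- function(model, backends = c("CFD", "RRE"), ...) {
  reports <- lapply(backends, function(b) run_pipeline(model, backend = b, ...))
  names(reports) <- backends
  pn <- names(reports[[1]]$delta)
  for (r in reports) {
    if (!identical(names(r$delta), pn)) {
      stop("backends disagree on the parameter axis", call. = FALSE)
    }
  }
  delta <- data.frame(parameter = pn, stringsAsFactors = FALSE)
  for (b in backends) delta[[b]] <- unname(reports[[b]]$delta[pn])
  subs <- reports[[1]]$subsets[, c("subset", "size")]
  coll <- subs
  for (b in backends) {
    coll[[b]] <- reports[[b]]$subsets$ci[match(subs$subset,
                                               reports[[b]]$subsets$subset)]
  }
  list(delta = delta, collinearity = coll, reports = reports)
}
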