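#' Concatenated non-dimensional sensitivity matrix
#'
#' Stacks the scale-free local sensitivities
#' \deqn{s_{ik}(t_\ell) = \frac{c_k}{E[X_i(t_\ell)]}
#'   \frac{\partial E[X_i(t_\ell)]}{\partial c_k}}
#' over all grid points and species into an `n x P` matrix with one row per
#' `(time, species)` cell and one column per parameter. The `t = 0` block
#' (where all sensitivities vanish identically) is dropped, and rows whose
#' mean `E[X_i(t_l)]` does not exceed `mask_tol` are dropped and logged
#' rather than producing non-finite entries.
#'
#' @param sens A sensitivity object from [fd_sensitivity()],
#'   [cle_sensitivity()] or [rre_sensitivity()].
#' @param params Named vector of the nominal parameter values `c` used for
#'   the non-dimensionalization; defaults to the values stored in `net` when
#'   supplied, otherwise must be given.
#' @param net Optional [reaction_network()] whose `params` supply `c`.
#' @param mask_tol Mean-masking tolerance; rows with `E[X] <= mask_tol` are
#'   dropped. Default `1e-8 * max(means)`.
#' @return A `"concat_sensitivity"` object: `matrix` (`n x P`), `row_index`
#'   (data frame of time/species per row), `mask_log` (dropped rows and
#'   why), `params`.
#' @export
concat_sensitivity <- function(sens, params = NULL, net = NULL,
                               mask_tol = NULL) {
  if (is.null(params)) {
    if (is.null(net)) {
      stop("supply 'params' (nominal parameter values) or 'net'",
           call. = FALSE)
    }
    params <- net$params
  }
  pn <- sens$param_names
  if (!all(pn %in% names(params))) {
    stop("'params' must name every parameter of the sensitivity object",
         call. = FALSE)
  }
  cvec <- params[pn]
  L <- length(sens$grid); N <- length(sens$species); P <- length(pn)
  means <- sens$means
  if (is.null(mask_tol)) mask_tol <- 1e-8 * max(means, 1)
  time <- rep(sens$grid, times = N)
  sp_lab <- rep(sens$species, each = L)
  flat <- matrix(sens$sens, L * N, P) # rows ordered species-major blocks
  keep_t0 <- time > 0
  keep_mean <- as.vector(means) > mask_tol
  keep <- keep_t0 & keep_mean
  if (!any(keep)) {
    stop("all rows were masked: no usable (time, species) cells", call. = FALSE)
  }
  mask_log <- data.frame(
    time = time[!keep], species = sp_lab[!keep],
    reason = ifelse(!keep_t0[!keep], "t0", "mean_below_tol"),
    stringsAsFactors = FALSE)
  s <- flat[keep, , drop = FALSE] * rep(cvec, each = sum(keep)) /
    as.vector(means)[keep]
  colnames(s) <- pn
  structure(
    list(matrix = s,
         row_index = data.frame(time = time[keep], species = sp_lab[keep],
                                stringsAsFactors = FALSE),
         n_rows = nrow(s), mask_log = mask_log, params = cvec,
         backend = sens$backend),
    class = "concat_sensitivity")
}

#' @export
print.concat_sensitivity <- function(x, ...) {
  cat("<concat_sensitivity> ", x$n_rows, " rows x ", ncol(x$matrix),
      " parameters (", nrow(x$mask_log), " rows masked)\n", sep = "")
  invisible(x)
}

as_sens_matrix <- function(x) {
  if (inherits(x, "concat_sensitivity")) return(x$matrix)
  if (inherits(x, "normalized_sensitivity")) return(x$matrix)
  as.matrix(x)
}

#' Root-mean-square parameter importance measure
#'
#' For each parameter `k`, the root-mean-square of column `k` of the
#' *un-normalized* non-dimensional sensitivity matrix,
#' \eqn{\delta_k^{msqr} = \sqrt{\frac{1}{n}\sum_i s_{ik}^2}}. A larger value
#' means perturbing `c_k` moves the mean state more; parameters below a
#' threshold (conventionally 0.2) are considered too uninfluential to
#' estimate.
#'
#' @param s A [concat_sensitivity()] object or plain numeric matrix.
#' @return Named vector of per-parameter importance measures.
#' @export
delta_msqr <- function(s) {
  m <- as_sens_matrix(s)
  sqrt(colMeans(m^2))
}

#' Column-normalize a sensitivity matrix
#'
#' Scales every column to unit Euclidean norm, the normalization under which
#' collinearity indices compare the *directions* of parameter effects.
#' Columns whose raw norm does not exceed `zero_tol` cannot be meaningfully
#' normalized (the model mean is insensitive to that parameter): they are
#' left as-is and flagged, and any collinearity index over a subset
#' containing them is reported as undefined (`NA`).
#'
#' @inheritParams delta_msqr
#' @param zero_tol Raw-column-norm threshold below which a column is
#'   flagged.
#' @return A `"normalized_sensitivity"` object: `matrix` with unit columns,
#'   `zero_columns` (names of flagged columns), `norms` (the raw norms).
#' @export
normalize_columns <- function(s, zero_tol = 1e-12) {
  m <- as_sens_matrix(s)
  norms <- sqrt(colSums(m^2))
  zero <- norms <= zero_tol
  scaled <- m
  scaled[, !zero] <- sweep(m[, !zero, drop = FALSE], 2, norms[!zero], "/")
  structure(
    list(matrix = scaled,
         zero_columns = colnames(m)[zero] %||% which(zero),
         norms = norms),
    class = "normalized_sensitivity")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

subset_cols <- function(m, subset) {
  if (is.character(subset)) {
    idx <- match(subset, colnames(m))
    if (anyNA(idx)) stop("unknown parameter in subset: ",
                         paste(subset[is.na(idx)], collapse = ", "),
                         call. = FALSE)
    idx
  } else {
    as.integer(subset)
  }
}

#' Collinearity index of a parameter subset
#'
#' For a subset `K` of parameters with unit-normalized sensitivity columns
#' `S_K`, the collinearity index is
#' \eqn{CI_K = 1 / \sqrt{\lambda_{\min}(S_K^T S_K)}
#'   = 1 / \min_{\|z\|=1} \|S_K z\|_2.}
#' It measures how nearly the columns are linearly dependent: a variation in
#' one parameter of a highly collinear set can be compensated by the others,
#' so the set cannot be estimated jointly. The conventional identifiability
#' cutoff is `CI_K < 20`.
#'
#' @param ns A [normalize_columns()] result (or a matrix already having
#'   unit columns).
#' @param subset Parameter names or column indices, at least 2.
#' @return The collinearity index; `NA` if the subset touches a flagged
#'   (zero-norm) column, `Inf` if the Gram matrix is numerically singular.
#' @examples
#' # two unit columns at correlation 0.75: CI = 1/sqrt(1 - 0.75) = 2
#' m <- cbind(a = c(1, 0), b = c(0.75, sqrt(1 - 0.75^2)))
#' collinearity_index(normalize_columns(m), c("a", "b"))
#' @export
collinearity_index <- function(ns, subset) {
  if (!inherits(ns, "normalized_sensitivity")) ns <- normalize_columns(ns)
  idx <- subset_cols(ns$matrix, subset)
  if (length(idx) < 2L) {
    stop("a collinearity index needs a subset of at least 2 parameters",
         call. = FALSE)
  }
  if (anyDuplicated(idx)) stop("subset indices must be distinct", call. = FALSE)
  flagged <- if (is.character(ns$zero_columns)) {
    match(ns$zero_columns, colnames(ns$matrix))
  } else {
    as.integer(ns$zero_columns)
  }
  if (any(idx %in% flagged)) return(NA_real_)
  g <- crossprod(ns$matrix[, idx, drop = FALSE])
  lmin <- min(eigen(g, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin <= .Machine$double.eps * length(idx)) return(Inf)
  1 / sqrt(lmin)
}

#' Singular spectrum and numerical rank of a sensitivity matrix
#'
#' The number of singular values above `rank_tol * sigma_1` estimates how
#' many parameter directions are independently constrained by the data: a
#' rank below the parameter count means some parameters are collinear and
#' cannot all be estimated.
#'
#' @inheritParams delta_msqr
#' @param rank_tol Relative tolerance for treating a singular value as zero;
#'   default `max(n, P) * machine epsilon`.
#' @return List with `values` (non-increasing singular values) and `rank`.
#' @export
svd_spectrum <- function(s, rank_tol = NULL) {
  m <- as_sens_matrix(s)
  d <- svd(m, nu = 0, nv = 0)$d
  if (is.null(rank_tol)) rank_tol <- max(dim(m)) * .Machine$double.eps
  list(values = d, rank = sum(d > rank_tol * d[1]))
}

#' Determinant measure of a parameter subset
#'
#' \eqn{\rho_K = \det(S_K^T S_K)^{1/(2k)}} for a subset of `k` columns: 1
#' for orthonormal columns, 0 for a singular subset. Used to compare the
#' joint estimability of competing subsets of the same size.
#'
#' @inheritParams collinearity_index
#' @export
determinant_measure <- function(ns, subset) {
  m <- as_sens_matrix(ns)
  idx <- subset_cols(m, subset)
  if (length(idx) < 1L) stop("subset must be non-empty", call. = FALSE)
  g <- crossprod(m[, idx, drop = FALSE])
  dt <- det(g)
  if (dt <= 0) return(0)
  dt^(1 / (2 * length(idx)))
}

#' Select identifiable parameter subsets
#'
#' Implements the subset-selection procedure: parameters are first ranked by
#' their importance measure and those with `delta <= delta_threshold` are
#' excluded (they cannot be estimated regardless of correlations); the
#' collinearity index is then computed for every subset of the ranked list
#' with `2 <= k <= max_subset_size`, and a subset is flagged identifiable
#' when `CI_K <= ci_threshold` and no member column is flagged undefined.
#'
#' @param ns A [normalize_columns()] result over the parameter axis.
#' @param delta Per-parameter importance measures from [delta_msqr()].
#' @param delta_threshold Importance cutoff (default 0.2).
#' @param ci_threshold Collinearity cutoff (default 20).
#' @param max_subset_size Largest subset size to enumerate; defaults to the
#'   number of ranked parameters. Enumeration is capped at 1e5 subsets.
#' @return An `"identifiability_report"` list: `delta`, `ranked_params`,
#'   `subsets` (data frame with `subset`, `size`, `ci`, `rho`,
#'   `identifiable`), `singular_values`, `rank` and the thresholds used.
#' @export
select_identifiable_subsets <- function(ns, delta, delta_threshold = 0.2,
                                        ci_threshold = 20,
                                        max_subset_size = NULL) {
  pn <- colnames(ns$matrix) %||% paste0("c", seq_len(ncol(ns$matrix)))
  ranked <- pn[delta > delta_threshold]
  ranked <- ranked[order(-delta[match(ranked, pn)])]
  if (length(ranked) == 0L) {
    warning("no parameter exceeds the importance threshold; nothing to rank")
    subsets <- data.frame(subset = character(), size = integer(),
                          ci = numeric(), rho = numeric(),
                          identifiable = logical(), stringsAsFactors = FALSE)
  } else {
    if (is.null(max_subset_size)) max_subset_size <- length(ranked)
    max_subset_size <- min(max_subset_size, length(ranked))
    sizes <- seq(2, max(2, max_subset_size))
    sizes <- sizes[sizes <= length(ranked)]
    n_total <- sum(choose(length(ranked), sizes))
    if (n_total > 1e5) {
      stop("subset enumeration budget exceeded (", n_total,
           " subsets); lower 'max_subset_size'", call. = FALSE)
    }
    rows <- list()
    for (k in sizes) {
      combs <- utils::combn(sort(match(ranked, pn)), k)
      for (ci_col in seq_len(ncol(combs))) {
        idx <- combs[, ci_col]
        ci_val <- collinearity_index(ns, idx)
        rho <- determinant_measure(ns, idx)
        rows[[length(rows) + 1L]] <- data.frame(
          subset = paste(pn[idx], collapse = " "),
          size = k, ci = ci_val, rho = rho,
          identifiable = !is.na(ci_val) && is.finite(ci_val) &&
            ci_val <= ci_threshold,
          stringsAsFactors = FALSE)
      }
    }
    subsets <- do.call(rbind, rows)
    subsets <- subsets[order(subsets$size, subsets$ci), ]
    rownames(subsets) <- NULL
  }
  sp <- svd_spectrum(ns$matrix)
  structure(
    list(delta = delta, ranked_params = ranked, subsets = subsets,
         singular_values = sp$values, rank = sp$rank,
         thresholds = list(delta = delta_threshold, ci = ci_threshold)),
    class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat("<identifiability_report>\n")
  cat("  delta_msqr: ",
      paste(sprintf("%s=%.3g", names(x$delta), x$delta), collapse = ", "),
      "\n", sep = "")
  cat("  ranked (delta > ", x$thresholds$delta, "): ",
      paste(x$ranked_params, collapse = ", "), "\n", sep = "")
  cat("  singular values: ",
      paste(sprintf("%.3g", x$singular_values), collapse = ", "),
      "  (rank ", x$rank, ")\n", sep = "")
  if (nrow(x$subsets)) {
    n_id <- sum(x$subsets$identifiable)
    cat("  subsets: ", nrow(x$subsets), " tested, ", n_id,
        " identifiable (CI <= ", x$thresholds$ci, ")\n", sep = "")
    print(utils::head(x$subsets, 10))
  }
  invisible(x)
}
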