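test_that("non-dimensionalization cancels proportional sensitivities", {
  # if S_ik = E[X_i]/c_k everywhere, every entry of s is exactly 1
  m <- model_fixture("infectious_disease")
  g <- time_grid(10, 6)
  means <- matrix(runif(12, 1, 50), 6, 2)
  cvec <- m$network$params
  sens <- array(0, c(6, 2, 5))
  for (k in 1:5) sens[, , k] <- means / cvec[k]
  fake <- structure(
    list(grid = g, species = c("S1", "S2"), param_names = names(cvec),
         sens = sens, means = means, backend = "TEST"),
    class = "fd_sensitivity")
  cs <- concat_sensitivity(fake, params = cvec)
  expect_equal(unname(cs$matrix), matrix(1, 10, 5))
  # the t = 0 block is dropped
  expect_true(all(cs$row_index$time > 0))
})

test_that("rows with vanishing means are masked, not propagated as NaN", {
  tg <- model_fixture("toggle_switch")
  rs <- rre_sensitivity(tg$network, tg$x0, time_grid(50, 11))
  cs <- concat_sensitivity(rs, params = tg$network$params)
  expect_true(all(is.finite(cs$matrix)))
  expect_true(all(cs$mask_log$time[cs$mask_log$reason == "t0"] == 0))
  expect_error(
    concat_sensitivity(rs, params = tg$network$params, mask_tol = 1e12),
    "all rows were masked")
})

test_that("the pure-death non-dimensional sensitivity is -c t", {
  g <- time_grid(2, 21)
  rs <- rre_sensitivity(pure_death(2), 20, g)
  cs <- concat_sensitivity(rs, params = c(c = 2))
  expect_equal(as.vector(cs$matrix), -2 * g[-1], tolerance = 1e-6)
})

test_that("delta_msqr is the column root mean square", {
  expect_equal(unname(delta_msqr(matrix(1, 7, 3))), rep(1, 3))
  expect_equal(delta_msqr(matrix(c(3, 4), 2, 1)), sqrt(25 / 2))
})

test_that("column normalization yields unit columns and flags dead ones", {
  m <- cbind(a = c(3, 4, 0), b = c(0, 0, 5), dead = c(0, 0, 0))
  ns <- normalize_columns(m)
  expect_equal(unname(colSums(ns$matrix[, 1:2]^2)), c(1, 1), tolerance = 1e-12)
  expect_equal(ns$zero_columns, "dead")
  expect_true(is.na(collinearity_index(ns, c("a", "dead"))))
  expect_false(is.na(collinearity_index(ns, c("a", "b"))))
})

test_that("collinearity index matches the two-column closed form", {
  # unit columns with inner product rho: lambda_min = 1 - |rho|
  for (rho in c(0, 0.3, 0.75, -0.6)) {
    m <- cbind(c(1, 0), c(rho, sqrt(1 - rho^2)))
    expect_equal(collinearity_index(normalize_columns(m), 1:2),
                 1 / sqrt(1 - abs(rho)), tolerance = 1e-10)
  }
  # orthonormal columns
  expect_equal(collinearity_index(normalize_columns(diag(3)), 1:3), 1)
  # exactly collinear columns
  m <- cbind(c(1, 0), c(1, 0))
  expect_equal(collinearity_index(normalize_columns(m), 1:2), Inf)
  expect_error(collinearity_index(normalize_columns(diag(3)), 1), "at least 2")
  expect_error(collinearity_index(normalize_columns(diag(3)), c(1, 1)),
               "distinct")
})

test_that("eigen-based index agrees with the direct minimization definition", {
  set.seed(11)
  for (rep in 1:5) {
    ns <- normalize_columns(random_unit_cols(40, 3))
    ci <- collinearity_index(ns, 1:3)
    z <- random_unit_cols(3, 3000) # random unit directions
    brute <- 1 / min(sqrt(colSums((ns$matrix %*% z)^2)))
    expect_lt(abs(ci - brute) / ci, 0.05)
    expect_gte(ci, brute) # discretized minimum cannot undershoot
  }
})

test_that("adding a parameter to a subset cannot decrease its collinearity index", {
  set.seed(12)
  for (rep in 1:100) {
    ns <- normalize_columns(random_unit_cols(25, 4))
    ci2 <- collinearity_index(ns, c(1, 2))
    ci3 <- collinearity_index(ns, c(1, 2, 3))
    ci4 <- collinearity_index(ns, 1:4)
    expect_lte(ci2, ci3 + 1e-10)
    expect_lte(ci3, ci4 + 1e-10)
  }
})

test_that("collinearity is scale-invariant but importance is not", {
  set.seed(13)
  m <- random_unit_cols(30, 3)
  scaled <- m
  scaled[, 2] <- scaled[, 2] * 37.5
  expect_equal(collinearity_index(normalize_columns(m), 1:3),
               collinearity_index(normalize_columns(scaled), 1:3),
               tolerance = 1e-10)
  expect_equal(delta_msqr(scaled)[2], 37.5 * delta_msqr(m)[2])
})

test_that("permuting the parameter axis permutes results without changing values", {
  set.seed(14)
  m <- random_unit_cols(30, 4)
  colnames(m) <- paste0("p", 1:4)
  perm <- c(3, 1, 4, 2)
  ns <- normalize_columns(m)
  nsp <- normalize_columns(m[, perm])
  expect_equal(unname(delta_msqr(m)[perm]), unname(delta_msqr(m[, perm])))
  expect_equal(collinearity_index(ns, c("p1", "p3")),
               collinearity_index(nsp, c("p1", "p3")))
})

test_that("the singular spectrum detects exact linear dependence", {
  sp <- svd_spectrum(diag(3))
  expect_equal(sp$values, rep(1, 3))
  expect_equal(sp$rank, 3)
  m <- random_unit_cols(20, 3)
  expect_equal(svd_spectrum(cbind(m, m[, 2]))$rank, svd_spectrum(m)$rank)
  expect_true(all(diff(svd_spectrum(cbind(m, m))$values) <= 1e-12))
})

test_that("the determinant measure grades orthogonality", {
  expect_equal(determinant_measure(diag(4), 1:4), 1)
  expect_equal(determinant_measure(cbind(c(1, 0), c(1, 0)), 1:2), 0)
  m <- cbind(c(1, 0), c(0.6, 0.8))
  expect_equal(determinant_measure(m, 1:2), (1 - 0.36)^(1 / 4))
})

test_that("subset selection ranks, enumerates and flags correctly", {
  # two orthogonal important parameters and one unimportant one
  m <- cbind(big1 = c(10, 0, 0), big2 = c(0, 10, 0), tiny = c(0, 0, 0.01))
  delta <- delta_msqr(m)
  ns <- normalize_columns(m)
  rep <- select_identifiable_subsets(ns, delta)
  expect_setequal(rep$ranked_params, c("big1", "big2"))
  expect_equal(nrow(rep$subsets), 1)
  expect_true(rep$subsets$identifiable)
  expect_equal(rep$subsets$ci, 1)
  # nothing important -> warning and empty table
  expect_warning(
    r0 <- select_identifiable_subsets(ns, c(0.01, 0.02, 0.001)),
    "no parameter")
  expect_equal(nrow(r0$subsets), 0)
  # combinatorial budget guard
  set.seed(15)
  wide <- random_unit_cols(30, 40)
  expect_error(
    select_identifiable_subsets(normalize_columns(wide), rep(1, 40)),
    "budget")
})
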