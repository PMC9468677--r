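ctx_default <- magnetic_context(m_v_a_per_m = 500, grad_b_t_per_m = 170,
                                b_mt = 530)

test_that("noiseless observables round-trip through the inverse fit", {
  obs <- forward_obs_list(1.2, 0.8)
  fit <- fit_shape(obs)
  expect_true(fit$converged)
  expect_true(fit$flattened)
  expect_lt(rel_err(fit$params$b, 1.2), 0.005)
  expect_lt(rel_err(fit$params$c, 0.8), 0.005)
  expect_lt(fit$residual, 1e-8)
})

test_that("surface tension is recovered end to end at known gamma", {
  gamma_true <- 20
  r0 <- 450
  c_um2 <- c_from_gamma(gamma_true, ctx_default)
  c_sc <- c_um2 * r0^2
  b_sc <- b_for_unit_volume(c_sc)
  obs_sc <- forward_obs_list(b_sc, c_sc)
  obs <- list(h = obs_sc$h * r0, w = obs_sc$w * r0, v = obs_sc$v * r0^3)
  fit <- fit_tension(obs, ctx_default)
  expect_lt(rel_err(fit$gamma_mn_per_m, gamma_true), 0.01)
})

test_that("an unflattened sphere yields a tension bound, not a number", {
  r <- 100
  obs <- list(h = 2 * r, w = 2 * r, v = 4 * pi * r^3 / 3)
  fit <- fit_tension(obs, ctx_default)
  expect_true(fit$converged)
  expect_false(fit$flattened)
  expect_lte(fit$params_scaled$c, fit$flat_threshold)
  expect_true(is.na(fit$gamma_mn_per_m))
  expect_true(is.finite(fit$gamma_lower_bound_mn_per_m))
  expect_gt(fit$gamma_lower_bound_mn_per_m, 0)
})

test_that("prolate observables are rejected as model mismatch", {
  expect_error(
    fit_shape(list(h = 220, w = 200, v = 4e6)),
    class = "tensiomag_input_error"
  )
})

test_that("the objective flattens in c as c tends to zero", {
  r <- 100
  obs <- list(h = 2 * r, w = 2 * r, v = 4 * pi * r^3 / 3)
  fit <- fit_shape(obs)
  f4 <- fit$objective(log(c(1, 1e-4)))
  f6 <- fit$objective(log(c(1, 1e-6)))
  expect_lt(abs(f4 - f6), 1e-6)
})

test_that("fitted c increases monotonically along a flattening sequence", {
  c_grid <- c(0.5, 1, 2, 4)
  fits <- vapply(c_grid, function(cc) {
    b <- b_for_unit_volume(cc)
    fit_shape(forward_obs_list(b, cc))$params_scaled$c
  }, numeric(1))
  expect_true(all(diff(fits) > 0))
})

test_that("capillary-constant/tension conversion is unit-exact and linear", {
  ctx1 <- magnetic_context(1, 1)          # f = 1 N/m^3
  expect_equal(gamma_from_c(1e-12, ctx1), 1000, tolerance = 1e-12)  # c = 1 m^-2
  ctx2 <- magnetic_context(2, 1)
  expect_equal(gamma_from_c(5e-6, ctx2), 2 * gamma_from_c(5e-6, ctx1),
               tolerance = 1e-12)
  expect_equal(c_from_gamma(gamma_from_c(3e-6, ctx_default), ctx_default),
               3e-6, tolerance = 1e-12)
  expect_error(gamma_from_c(0, ctx1), class = "tensiomag_input_error")
  expect_error(gamma_from_c(-1, ctx1), class = "tensiomag_input_error")
})

test_that("malformed observables are rejected", {
  expect_error(fit_shape(list(h = 1, w = 2)), class = "tensiomag_input_error")
  expect_error(fit_shape(list(h = -1, w = 2, v = 1)),
               class = "tensiomag_input_error")
  expect_error(fit_tension(list(h = 1, w = 2, v = NA), ctx_default),
               class = "tensiomag_input_error")
})

test_that("tidy and glance expose the fit in broom shape", {
  obs <- forward_obs_list(1.1, 1.5)
  fit <- fit_tension(obs, ctx_default)
  td <- tidy(fit)
  expect_identical(td$term, c("b", "c", "gamma"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_equal(gl$gamma_mn_per_m,
               gamma_from_c(fit$params$c, ctx_default), tolerance = 1e-12)
})

test_that("fit_tension_each maps over a tidy observables table", {
  rows <- dplyr::bind_rows(
    tibble::tibble(condition = "A", !!!forward_obs_list(1.2, 1)),
    tibble::tibble(condition = "B", !!!forward_obs_list(1.05, 3))
  )
  res <- fit_tension_each(rows, ctx_default)
  expect_identical(nrow(res), 2L)
  expect_identical(res$condition, c("A", "B"))
  expect_true(all(res$converged))
  # more flattened input must fit a larger capillary constant
  expect_gt(res$c_per_um2[2], res$c_per_um2[1])
})
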