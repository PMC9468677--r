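test_that("force-free profiles reproduce the sphere closed form", {
  for (b in c(1, 2)) {
    prof <- integrate_profile(shape_params(b, 0))
    obs <- compute_observables(prof)
    r <- 1 / b
    expect_lt(rel_err(obs$h, 2 * r), 1e-6)
    expect_lt(rel_err(obs$w, 2 * r), 1e-6)
    expect_lt(rel_err(obs$v, 4 * pi * r^3 / 3), 1e-6)
    expect_lt(rel_err(max(prof$s), pi * r), 1e-5)
    expect_lt(rel_err(max(prof$x), r), 1e-5)
  }
})

test_that("invalid shape parameters are rejected", {
  expect_error(shape_params(0, 1), class = "tensiomag_input_error")
  expect_error(shape_params(-1, 0), class = "tensiomag_input_error")
  expect_error(shape_params(1, -0.5), class = "tensiomag_input_error")
  expect_error(nondimensionalize(shape_params(1, 1), 0),
               class = "tensiomag_input_error")
  expect_error(redimensionalize(shape_params(1, 1), -2),
               class = "tensiomag_input_error")
})

test_that("integrated profiles satisfy the curve invariants", {
  cases <- list(c(1, 0), c(1, 0.5), c(0.8, 3), c(2.5, 5))
  for (pc in cases) {
    prof <- integrate_profile(shape_params(pc[1], pc[2]))
    expect_identical(prof$s[1], 0)
    expect_identical(prof$x[1], 0)
    expect_identical(prof$z[1], 0)
    expect_identical(prof$phi[1], 0)
    expect_true(all(diff(prof$s) > 0))
    expect_true(all(prof$x >= 0))
    expect_true(all(diff(prof$z) >= 0))
    expect_true(all(prof$phi >= 0 & prof$phi <= pi + 1e-12))
    expect_gte(prof$phi[nrow(prof)], pi - 1e-6)
  }
})

test_that("adaptive integration agrees with the fixed-step RK4 reference", {
  a <- integrate_profile(shape_params(1, 0.5))
  r <- integrate_profile_rk4(shape_params(1, 0.5), step = 1e-5)
  oa <- compute_observables(a)
  or <- compute_observables(r)
  expect_lt(rel_err(oa$h, or$h), 1e-6)           # terminal z
  expect_lt(rel_err(tail(a$x, 1), tail(r$x, 1)), 1e-6)  # terminal x
  expect_lt(rel_err(oa$w, or$w), 1e-6)
  expect_lt(rel_err(oa$v, or$v), 1e-6)
})

test_that("integrated volume agrees with trapezoid quadrature", {
  ref <- integrate_profile_rk4(shape_params(1, 1), step = 1e-5, thin = 50L)
  v_quad <- trapz_volume(ref)
  oa <- compute_observables(integrate_profile(shape_params(1, 1)))
  expect_lt(rel_err(oa$v, v_quad), 1e-5)
})

test_that("observables fall back to quadrature for bare curves", {
  prof <- integrate_profile(shape_params(1.3, 0.7), n_out = 2001L)
  bare <- tibble::as_tibble(prof)  # drops the observables attribute
  class(bare) <- c("profile_curve", class(bare))
  ob <- compute_observables(bare)
  oa <- compute_observables(prof)
  expect_lt(rel_err(ob$h, oa$h), 1e-8)
  expect_lt(rel_err(ob$w, oa$w), 1e-6)
  expect_lt(rel_err(ob$v, oa$v), 1e-5)
})

test_that("unclosed profiles are rejected", {
  prof <- integrate_profile(shape_params(1, 0.5))
  cut <- prof[prof$phi < 2, ]
  class(cut) <- c("profile_curve", class(cut))
  expect_error(compute_observables(cut), class = "tensiomag_input_error")
})

test_that("nondimensionalization is exact arithmetic and invertible", {
  p <- nondimensionalize(shape_params(0.01, 4e-6), 100)
  expect_equal(p$b, 1, tolerance = 1e-14)
  expect_equal(p$c, 0.04, tolerance = 1e-14)
  q <- shape_params(0.734, 2.19)
  rt <- redimensionalize(nondimensionalize(q, 311.7), 311.7)
  expect_equal(rt$b, q$b, tolerance = 1e-14)
  expect_equal(rt$c, q$c, tolerance = 1e-14)
})

test_that("the dimensionless shape map is scale invariant", {
  b_sc <- 1.3; c_sc <- 0.7; r <- 250
  scaled <- forward_obs_list(b_sc, c_sc)
  dimensional <- forward_obs_list(b_sc / r, c_sc / r^2)
  expect_lt(rel_err(dimensional$h, scaled$h * r), 1e-8)
  expect_lt(rel_err(dimensional$w, scaled$w * r), 1e-8)
  expect_lt(rel_err(dimensional$v, scaled$v * r^3), 1e-8)
})

test_that("profile CSV round-trips through its serialization", {
  prof <- integrate_profile(shape_params(1, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  back <- read_profile_csv(path)
  expect_equal(back$s, prof$s, tolerance = 1e-12)
  expect_equal(back$phi, prof$phi, tolerance = 1e-12)
  obs <- compute_observables(back)
  expect_lt(rel_err(obs$v, compute_observables(prof)$v), 1e-5)
})
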