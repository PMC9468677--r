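# render a sphere profile (radius r_um) for reuse across cases
sphere_profile <- function(r_um) integrate_profile(shape_params(1 / r_um, 0))

test_that("a rendered disk segments to the expected area", {
  n <- 301L
  cc <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - cc)^2, (seq_len(n) - cc)^2, `+`))
  img <- side_view_image(matrix(0.85, n, n) - 0.7 * (d <= 100), 1)
  mask <- segment_aggregate(img)
  expect_lt(abs(sum(mask) - pi * 100^2) / (pi * 100^2), 0.01)
})

test_that("blank and border-touching images raise extraction errors", {
  blank <- side_view_image(matrix(0.5, 50, 50), 1)
  expect_error(segment_aggregate(blank), class = "tensiomag_input_error")
  touching <- matrix(0.9, 50, 50)
  touching[20:30, 1:30] <- 0.1
  expect_error(segment_aggregate(side_view_image(touching, 1)),
               class = "tensiomag_input_error")
})

test_that("segmentation is robust to blur and noise (IoU >= 0.98)", {
  prof <- sphere_profile(80)
  clean <- render_profile_image(prof, scale_um_per_px = 1)
  truth <- clean$pixels < 0.5
  noisy <- render_profile_image(prof, scale_um_per_px = 1,
                                blur_sigma_px = 2, noise_sd = 0.05,
                                seed = 1)
  mask <- segment_aggregate(noisy)
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.98)
})

test_that("segmentation handles bright-on-dark polarity automatically", {
  prof <- sphere_profile(40)
  img <- render_profile_image(prof, scale_um_per_px = 1,
                              fg = 0.9, bg = 0.1)
  mask <- segment_aggregate(img)
  expect_lt(abs(sum(mask) - pi * 40^2) / (pi * 40^2), 0.05)
})

test_that("a rendered sphere yields its geometry to pixel accuracy", {
  r <- 100
  img <- render_profile_image(sphere_profile(r), scale_um_per_px = 1)
  geo <- extract_geometry(img)
  expect_lte(abs(geo$observables$h - 2 * r), 1)
  expect_lte(abs(geo$observables$w - 2 * r), 1)
  expect_lt(rel_err(geo$observables$v, 4 * pi * r^3 / 3), 0.02)
})

test_that("a rendered flattened profile yields model geometry", {
  r_eq <- 400
  scale <- 0.5
  b_sc <- 1.1; c_sc <- 2.0
  prof_sc <- integrate_profile(shape_params(b_sc, c_sc))
  prof <- integrate_profile(shape_params(b_sc / r_eq, c_sc / r_eq^2))
  truth <- compute_observables(prof)
  img <- render_profile_image(prof, scale_um_per_px = scale)
  geo <- extract_geometry(img)
  expect_lte(abs(geo$observables$h - truth$h), scale)
  expect_lte(abs(geo$observables$w - truth$w), scale)
  expect_lt(rel_err(geo$observables$v, truth$v), 0.02)

  # doubling the resolution tightens the physical estimates
  img2 <- render_profile_image(prof, scale_um_per_px = scale / 2)
  geo2 <- extract_geometry(img2)
  expect_lte(abs(geo2$observables$h - truth$h), scale / 2)
  expect_lte(abs(geo2$observables$w - truth$w), scale / 2)
  expect_lt(rel_err(geo2$observables$v, truth$v), 0.01)
})

test_that("symmetric renders report near-zero asymmetry", {
  img <- render_profile_image(sphere_profile(60), scale_um_per_px = 1)
  geo <- extract_geometry(img)
  expect_lte(geo$asymmetry, 0.01)
})

test_that("image files round-trip through read_side_view", {
  img <- render_profile_image(sphere_profile(30), scale_um_per_px = 1)
  path <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(t(img$pixels)), path)
  back <- read_side_view(path, 1)
  expect_equal(dim(back$pixels), dim(img$pixels))
  expect_lt(max(abs(back$pixels - img$pixels)), 0.01)
  geo <- extract_geometry(back)
  expect_lte(abs(geo$observables$w - 60), 1)
})
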