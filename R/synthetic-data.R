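#' Render a meridional profile to a grayscale side-view image
#'
#' Draws the solid of revolution described by a closed profile as a
#' dark object on a bright background, as seen from the side with the
#' substrate at the bottom of the frame, optionally blurred and
#' corrupted with Gaussian pixel noise.
#'
#' @param profile A closed `profile_curve` in micrometres.
#' @param scale_um_per_px Pixel size (um/px).
#' @param margin_um Background margin around the object.
#' @param fg,bg Foreground (object) and background intensities.
#' @param blur_sigma_px Gaussian blur sigma in px (0 = none).
#' @param noise_sd Gaussian pixel-noise standard deviation (0 = none).
#' @param seed Optional seed; a fixed seed gives a bit-identical image.
#' @return A [side_view_image()].
#' @export
render_profile_image <- function(profile, scale_um_per_px = 1,
                                 margin_um = 50, fg = 0.15, bg = 0.85,
                                 blur_sigma_px = 0, noise_sd = 0,
                                 seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  obs <- compute_observables(profile)
  h <- obs$h; w <- obs$w
  # radius as a function of depth below the apex (z monotone in s)
  zz <- profile$z; xx <- profile$x
  keep <- c(TRUE, diff(zz) > 0)
  r_of_z <- function(z) approx(zz[keep], xx[keep], z, rule = 2)$y

  n_col <- 2L * ceiling((w / 2 + margin_um) / scale_um_per_px) + 1L
  n_row <- ceiling((h + 2 * margin_um) / scale_um_per_px)
  axis_px <- (n_col + 1) / 2
  z_top <- margin_um
  z_rows <- (seq_len(n_row) - 0.5) * scale_um_per_px - z_top
  x_cols <- (seq_len(n_col) - axis_px) * scale_um_per_px

  r_rows <- numeric(n_row)
  inside <- z_rows >= 0 & z_rows <= h
  r_rows[inside] <- r_of_z(z_rows[inside])
  mask <- outer(r_rows, abs(x_cols), `>=`) & inside

  img <- matrix(bg, n_row, n_col)
  img[mask] <- fg
  if (blur_sigma_px > 0) {
    img <- t(EBImage::imageData(
      EBImage::gblur(EBImage::Image(t(img)), sigma = blur_sigma_px)
    ))
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(length(img), 0, noise_sd),
                                        n_row, n_col)
  img <- pmin(pmax(img, 0), 1)
  side_view_image(img, scale_um_per_px)
}

#' Synthesize a side-view image of a flattened aggregate
#'
#' Generates the equilibrium shape of an aggregate of known surface
#' tension under the magnetic body force and renders it: the capillary
#' constant is `c = M_V grad(B) / gamma`, and the apex curvature is
#' solved so the aggregate volume equals that of the unflattened
#' sphere of radius `r0_um`.  Ground truth is returned alongside the
#' image, making the render -> extract -> fit loop checkable.
#'
#' @param gamma_mn_per_m True surface tension (mN/m).
#' @param ctx A [magnetic_context()].
#' @param r0_um Radius of the unflattened spheroid (um).
#' @param scale_um_per_px,blur_sigma_px,noise_sd,margin_um,seed Passed
#'   to [render_profile_image()].
#' @return A list with `image` (a [side_view_image()]), `truth` (list
#'   `b`, `c` (1/um, 1/um^2), `h`, `w`, `v` (um), `gamma_mn_per_m`,
#'   `sphere_like`), and `profile` (the generating curve, um).  When
#'   the flattening `w - h` is below one pixel the `sphere_like` flag
#'   is set (the tension is effectively unresolvable from the image).
#' @export
synth_aggregate_image <- function(gamma_mn_per_m, ctx, r0_um = 450,
                                  scale_um_per_px = 1, blur_sigma_px = 0,
                                  noise_sd = 0, margin_um = 50,
                                  seed = NULL) {
  stopifnot(inherits(ctx, "magnetic_context"))
  c_um2 <- c_from_gamma(gamma_mn_per_m, ctx)
  c_sc <- c_um2 * r0_um^2
  # apex curvature preserving the molded volume 4/3 pi r0^3
  f <- function(b) forward_observables(b, c_sc)[["v"]] - 4 * pi / 3
  b_sc <- uniroot(f, c(0.05, 5), extendInt = "downX", tol = 1e-9)$root
  prof_sc <- integrate_profile(shape_params(b_sc, c_sc))
  prof <- prof_sc
  prof$s <- prof$s * r0_um; prof$x <- prof$x * r0_um; prof$z <- prof$z * r0_um
  obs_sc <- attr(prof_sc, "observables")
  attr(prof, "observables") <- list(h = obs_sc$h * r0_um, w = obs_sc$w * r0_um,
                                    v = obs_sc$v * r0_um^3)
  attr(prof, "params") <- shape_params(b_sc / r0_um, c_um2)

  obs <- attr(prof, "observables")
  sphere_like <- (obs$w - obs$h) < scale_um_per_px
  if (sphere_like) {
    warn("flattening is below one pixel; image is sphere-like and gamma will not be resolvable.")
  }
  img <- render_profile_image(prof, scale_um_per_px = scale_um_per_px,
                              margin_um = margin_um,
                              blur_sigma_px = blur_sigma_px,
                              noise_sd = noise_sd, seed = seed)
  list(
    image = img,
    truth = list(b = b_sc / r0_um, c = c_um2, h = obs$h, w = obs$w, v = obs$v,
                 gamma_mn_per_m = gamma_mn_per_m, sphere_like = sphere_like),
    profile = prof
  )
}

#' Synthesize an AFM cell-cell force curve
#'
#' Approach ramp to the contact force, constant-height dwell with
#' exponential relaxation, and a retraction whose contact release
#' decays quickly and then shows a Gaussian adhesion dip of known
#' depth.  An affine baseline (offset + drift) and white noise are
#' added on top, so baseline correction and dip recovery can be tested
#' against ground truth.
#'
#' @param dip_nn True detachment dip depth (nN).
#' @param noise_sd_nn White-noise standard deviation (nN).
#' @param drift_nn_per_s Linear baseline drift (nN/s).
#' @param offset_nn Constant baseline offset (nN).
#' @param contact_nn Contact force setpoint (nN).
#' @param rate_hz Sampling rate.
#' @param approach_s,dwell_s,retract_s Segment durations (s).
#' @param dip_center_s Dip position within the retract segment (s).
#' @param dip_width_s Gaussian dip width (s).
#' @param retract_um_per_s Retraction speed (um/s).
#' @param seed Optional seed for reproducibility.
#' @return A [as_force_curve()] tibble.
#' @export
synth_force_curve <- function(dip_nn = 1.8, noise_sd_nn = 0.1,
                              drift_nn_per_s = 0, offset_nn = 0,
                              contact_nn = 5, rate_hz = 500,
                              approach_s = 1, dwell_s = 2, retract_s = 2,
                              dip_center_s = 0.5, dip_width_s = 0.1,
                              retract_um_per_s = 5, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  dt <- 1 / rate_hz
  t_app <- seq(0, approach_s - dt, by = dt)
  t_dwe <- seq(approach_s, approach_s + dwell_s - dt, by = dt)
  t_ret <- seq(approach_s + dwell_s,
               approach_s + dwell_s + retract_s - dt, by = dt)
  f_app <- contact_nn * t_app / approach_s
  f_dwe <- contact_nn * (0.8 + 0.2 * exp(-(t_dwe - approach_s) / 5))
  tr <- t_ret - min(t_ret)
  f_ret <- contact_nn * 0.8 * exp(-tr / 0.05) -
    dip_nn * exp(-(tr - dip_center_s)^2 / (2 * dip_width_s^2))
  tt <- c(t_app, t_dwe, t_ret)
  ff <- c(f_app, f_dwe, f_ret) + offset_nn + drift_nn_per_s * tt
  if (noise_sd_nn > 0) ff <- ff + rnorm(length(ff), 0, noise_sd_nn)
  hh <- c(
    5 - 5 * t_app / approach_s,
    rep(0, length(t_dwe)),
    retract_um_per_s * tr
  )
  as_force_curve(tibble(
    time_s = tt, height_um = hh, force_nn = ff,
    segment = rep(c("approach", "dwell", "retract"),
                  c(length(t_app), length(t_dwe), length(t_ret)))
  ))
}

#' Synthesize a shrinking scratch-wound series
#'
#' A vertical wound strip whose area shrinks to match target coverage
#' fractions at the given timepoints, with ragged (jittered) edges and
#' multiplicative noise on the realized coverage.  The `t = 0` mask is
#' always present.
#'
#' @param coverage_by_time Named numeric vector: names are timepoints
#'   in hours (must include `"0"` with value 0), values are target
#'   coverage fractions in `[0, 1]`.
#' @param dim Image dimensions (rows, cols) in px.
#' @param wound_frac Initial wound width as a fraction of the image width.
#' @param edge_jitter_px Per-row edge raggedness (px, sd).
#' @param coverage_noise_sd Noise on the realized coverage fraction.
#' @param seed Optional seed.
#' @return A list with `masks` (list of logical matrices, wound = TRUE,
#'   named by timepoint) and `areas` (tibble `time_h`, `area` in px^2).
#' @export
synth_wound_series <- function(coverage_by_time = c(`0` = 0, `24` = 0.55,
                                                    `48` = 0.9),
                               dim = c(120L, 160L), wound_frac = 0.3,
                               edge_jitter_px = 2, coverage_noise_sd = 0.03,
                               seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  tp <- as.numeric(names(coverage_by_time))
  if (!any(tp == 0)) abort_input("coverage_by_time must include timepoint 0.")
  if (any(coverage_by_time < 0 | coverage_by_time > 1)) {
    abort_input("coverage targets must lie in [0, 1].")
  }
  w0 <- wound_frac * dim[2L]
  centre <- dim[2L] / 2
  masks <- purrr::map(seq_along(tp), function(i) {
    cov <- coverage_by_time[[i]]
    if (tp[i] > 0) {
      cov <- min(max(cov + rnorm(1, 0, coverage_noise_sd), 0), 1)
    }
    half <- w0 * (1 - cov) / 2
    jit <- rnorm(dim[1L], 0, edge_jitter_px)
    mask <- matrix(FALSE, dim[1L], dim[2L])
    for (r in seq_len(dim[1L])) {
      lo <- max(1, round(centre - half + jit[r]))
      hi <- min(dim[2L], round(centre + half + jit[r]))
      if (half > 0.5 && hi >= lo) mask[r, lo:hi] <- TRUE
    }
    mask
  })
  names(masks) <- names(coverage_by_time)
  areas <- tibble(
    time_h = tp,
    area = unname(purrr::map_dbl(masks, wound_area))
  )
  list(masks = masks, areas = areas)
}

#' Synthesize per-field transwell invasion counts
#'
#' Poisson-distributed invading-cell counts per microscope field.
#'
#' @param mean_per_field Expected invading cells per field.
#' @param n_fields Fields imaged per replicate.
#' @param n_replicates Independent biological replicates.
#' @param condition Condition label.
#' @param seed Optional seed.
#' @return A tibble `condition`, `replicate`, `field`, `count`.
#' @export
synth_invasion_counts <- function(mean_per_field, n_fields = 5L,
                                  n_replicates = 3L, condition = "NT",
                                  seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (mean_per_field < 0) abort_input("`mean_per_field` must be >= 0.")
  tidyr::expand_grid(
    condition = condition,
    replicate = seq_len(n_replicates),
    field = seq_len(n_fields)
  ) %>%
    mutate(count = rpois(dplyr::n(), mean_per_field))
}
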