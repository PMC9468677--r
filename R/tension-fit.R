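#' Magnetic calibration context
#'
#' The body-force density acting on a magnetically labeled aggregate is
#' `f = M_V * grad(B)` (N/m^3), where `M_V` is the magnetic moment per
#' unit volume of the tissue (A/m, from vibrating-sample magnetometry)
#' and `grad(B)` is the field gradient of the permanent magnet (T/m).
#' The field magnitude `B` is informational only: the force depends on
#' the gradient.
#'
#' @param m_v_a_per_m Magnetic moment per unit volume, A/m, > 0.
#' @param grad_b_t_per_m Field gradient, T/m, > 0.
#' @param b_mt Optional field magnitude, mT (metadata only).
#' @return An object of class `magnetic_context` with the derived
#'   `force_density_n_per_m3`.
#' @examples
#' magnetic_context(m_v_a_per_m = 500, grad_b_t_per_m = 170, b_mt = 530)
#' @export
magnetic_context <- function(m_v_a_per_m, grad_b_t_per_m, b_mt = NULL) {
  for (nm in c("m_v_a_per_m", "grad_b_t_per_m")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort_input(sprintf("`%s` must be a single finite value > 0.", nm))
    }
  }
  structure(
    list(
      m_v_a_per_m = as.numeric(m_v_a_per_m),
      grad_b_t_per_m = as.numeric(grad_b_t_per_m),
      b_mt = if (is.null(b_mt)) NA_real_ else as.numeric(b_mt),
      force_density_n_per_m3 = as.numeric(m_v_a_per_m) * as.numeric(grad_b_t_per_m)
    ),
    class = "magnetic_context"
  )
}

#' @export
print.magnetic_context <- function(x, ...) {
  cat(sprintf(
    "<magnetic_context> M_V = %g A/m, grad(B) = %g T/m (f = %g N/m^3)\n",
    x$m_v_a_per_m, x$grad_b_t_per_m, x$force_density_n_per_m3
  ))
  invisible(x)
}

#' Convert between capillary constant and surface tension
#'
#' The capillary constant is `c = M_V * grad(B) / gamma`.  With `c` in
#' 1/um^2 and the force density in N/m^3, the surface tension in mN/m
#' is `gamma = f * 1e-9 / c` (1 N/m = 1000 mN/m; 1 um^-2 = 1e12 m^-2).
#'
#' @param c_per_um2 Capillary constant, 1/um^2, > 0.
#' @param gamma_mn_per_m Surface tension, mN/m, > 0.
#' @param ctx A [magnetic_context()].
#' @return `gamma_from_c()`: surface tension in mN/m.
#'   `c_from_gamma()`: capillary constant in 1/um^2.
#' @examples
#' ctx <- magnetic_context(500, 170)
#' gamma_from_c(c_from_gamma(16, ctx), ctx)  # 16 mN/m
#' @export
gamma_from_c <- function(c_per_um2, ctx) {
  stopifnot(inherits(ctx, "magnetic_context"))
  if (any(!is.finite(c_per_um2)) || any(c_per_um2 <= 0)) {
    abort_input("`c_per_um2` must be finite and > 0 (aggregate not measurably flattened).")
  }
  ctx$force_density_n_per_m3 * 1e-9 / c_per_um2
}

#' @rdname gamma_from_c
#' @export
c_from_gamma <- function(gamma_mn_per_m, ctx) {
  stopifnot(inherits(ctx, "magnetic_context"))
  if (any(!is.finite(gamma_mn_per_m)) || any(gamma_mn_per_m <= 0)) {
    abort_input("`gamma_mn_per_m` must be finite and > 0.")
  }
  ctx$force_density_n_per_m3 * 1e-9 / gamma_mn_per_m
}

as_observables_row <- function(obs) {
  if (is.data.frame(obs)) {
    if (nrow(obs) != 1L) {
      abort_input("`obs` must be a single observation (one row with h, w, v).")
    }
    obs <- as.list(obs)
  }
  obs <- obs[c("h", "w", "v")]
  if (any(vapply(obs, is.null, logical(1))) ||
      !all(vapply(obs, function(u) is.numeric(u) && is.finite(u) && u > 0,
                  logical(1)))) {
    abort_input("`obs` must supply finite positive `h`, `w`, `v`.")
  }
  lapply(obs, as.numeric)
}

#' Fit shape parameters to measured height, width and volume
#'
#' Inverse problem of [integrate_profile()]: finds the apex curvature
#' `b` and capillary constant `c` whose equilibrium profile reproduces
#' the observed height `h`, width `w` and volume `V`.  The objective is
#' the sum over the three observables of squared relative errors
#' (dimensionless, so the three contribute comparably), minimized over
#' `(b, c)` scaled by the equivalent radius `R_eq = (3 V_obs/4 pi)^(1/3)`.
#'
#' Initialization evaluates a log-spaced grid over the scaled capillary
#' constant, solving at each grid point for the `b` that matches the
#' observed volume; the best grid point seeds a Nelder-Mead refinement
#' in log-parameters.  A fitted scaled `c` below `flat_threshold` means
#' the flattening is below measurement resolution: the shape is then
#' indistinguishable from a sphere, `c` is not identified (only bounded
#' above), and downstream the surface tension is reported as a lower
#' bound rather than a number.
#'
#' @param obs A one-row data frame or named list/vector with `h`, `w`,
#'   `v` in consistent length units.
#' @param c_grid Grid of scaled capillary constants for initialization.
#' @param flat_threshold Scaled-`c` detection floor for "not measurably
#'   flattened".
#' @param prolate_tol The model cannot produce prolate shapes (`h > w`)
#'   for `c >= 0`; inputs with `h > w * (1 + prolate_tol)` are rejected.
#' @param reltol Relative convergence tolerance on the objective.
#' @param maxit Maximum Nelder-Mead iterations.
#' @return An object of class `shape_fit`: a list with elements
#'   `params` (dimensional [shape_params()]), `params_scaled`, `r_eq`,
#'   `predicted` (one-row tibble `h`, `w`, `v`), `residual`,
#'   `converged`, `flattened`, `n_eval`, and `objective` (the scaled
#'   objective function, exposed for diagnostics).
#' @export
fit_shape <- function(obs, c_grid = 10^seq(-3, 2, length.out = 11),
                      flat_threshold = 1e-3, prolate_tol = 0.02,
                      reltol = 1e-10, maxit = 400L) {
  obs <- as_observables_row(obs)
  if (obs$h > obs$w * (1 + prolate_tol)) {
    abort_input(paste0(
      "model mismatch: observed h > w (prolate shape); the flattening ",
      "model only produces oblate shapes for c >= 0."
    ))
  }
  r_eq <- equivalent_radius(obs$v)
  target <- c(h = obs$h / r_eq, w = obs$w / r_eq, v = 4 * pi / 3)
  n_eval <- 0L

  objective <- function(par_log) {
    b <- exp(par_log[[1L]]); cc <- exp(par_log[[2L]])
    n_eval <<- n_eval + 1L
    pred <- tryCatch(forward_observables(b, cc),
                     error = function(e) NULL)
    if (is.null(pred)) return(1e10)
    sum(((pred - target) / target)^2)
  }

  # b that reproduces the target volume at a given c (V decreasing in b)
  b_matching_volume <- function(cc) {
    f <- function(b) forward_observables(b, cc)[["v"]] - target[["v"]]
    lo <- 0.05; hi <- 5
    flo <- f(lo); fhi <- f(hi)
    while (flo < 0 && lo > 1e-4) { lo <- lo / 4; flo <- f(lo) }
    while (fhi > 0 && hi < 100) { hi <- hi * 4; fhi <- f(hi) }
    if (flo < 0 || fhi > 0) return(NA_real_)
    uniroot(f, c(lo, hi), tol = 1e-5)$root
  }

  starts <- purrr::map(c_grid, function(cc) {
    b <- tryCatch(b_matching_volume(cc), error = function(e) NA_real_)
    if (!is.finite(b)) return(NULL)
    par <- log(c(b, cc))
    list(par = par, value = objective(par))
  })
  starts <- purrr::compact(starts)
  if (length(starts) == 0L) {
    abort_convergence("no valid starting point found on the initialization grid.")
  }
  best <- starts[[which.min(purrr::map_dbl(starts, "value"))]]

  opt <- optim(best$par, objective, method = "Nelder-Mead",
               control = list(reltol = reltol, maxit = maxit))
  b_sc <- exp(opt$par[[1L]]); c_sc <- exp(opt$par[[2L]])
  flattened <- c_sc >= flat_threshold
  params_scaled <- shape_params(b_sc, c_sc)
  params <- redimensionalize(params_scaled, r_eq)
  pred_sc <- forward_observables(b_sc, c_sc)

  structure(
    list(
      params = params,
      params_scaled = params_scaled,
      r_eq = r_eq,
      predicted = tibble(h = pred_sc[["h"]] * r_eq, w = pred_sc[["w"]] * r_eq,
                         v = pred_sc[["v"]] * r_eq^3),
      observed = tibble(h = obs$h, w = obs$w, v = obs$v),
      residual = opt$value,
      converged = opt$convergence == 0L,
      flattened = flattened,
      flat_threshold = flat_threshold,
      n_eval = n_eval,
      objective = objective
    ),
    class = "shape_fit"
  )
}

#' @export
print.shape_fit <- function(x, ...) {
  cat(sprintf(
    "<shape_fit> b = %.6g, c = %.6g (R_eq = %.4g); residual %.3g; %s%s\n",
    x$params$b, x$params$c, x$r_eq, x$residual,
    if (x$converged) "converged" else "NOT converged",
    if (x$flattened) "" else "; not measurably flattened"
  ))
  invisible(x)
}

#' Fit surface tension from flattened-aggregate observables
#'
#' Composition of [fit_shape()] and [gamma_from_c()]: fits `(b, c)` to
#' the observed `(h, w, V)` and converts the capillary constant to a
#' surface tension using the magnetic calibration.  When the fitted
#' shape is not measurably flattened (scaled `c` below the detection
#' floor), `gamma_mn_per_m` is `NA` and `gamma_lower_bound_mn_per_m`
#' carries the implied bound instead.
#'
#' @inheritParams fit_shape
#' @param ctx A [magnetic_context()].
#' @param ... Passed on to [fit_shape()].
#' @return An object of class `tension_fit` extending the `shape_fit`
#'   list with `gamma_mn_per_m`, `gamma_lower_bound_mn_per_m` and the
#'   calibration `ctx`.  Lengths in `obs` are interpreted as
#'   micrometres for the unit conversion.
#' @examples
#' \donttest{
#' ctx <- magnetic_context(500, 170)
#' prof <- integrate_profile(shape_params(1 / 400, c_from_gamma(16, ctx)))
#' fit_tension(compute_observables(prof), ctx)
#' }
#' @export
fit_tension <- function(obs, ctx, ...) {
  stopifnot(inherits(ctx, "magnetic_context"))
  fit <- fit_shape(obs, ...)
  c_floor_um2 <- fit$flat_threshold / fit$r_eq^2
  if (fit$flattened && fit$converged) {
    fit$gamma_mn_per_m <- gamma_from_c(fit$params$c, ctx)
    fit$gamma_lower_bound_mn_per_m <- NA_real_
  } else {
    fit$gamma_mn_per_m <- NA_real_
    fit$gamma_lower_bound_mn_per_m <- gamma_from_c(c_floor_um2, ctx)
  }
  fit$ctx <- ctx
  class(fit) <- c("tension_fit", class(fit))
  fit
}

#' @export
print.tension_fit <- function(x, ...) {
  if (is.finite(x$gamma_mn_per_m)) {
    cat(sprintf("<tension_fit> gamma = %.4g mN/m\n", x$gamma_mn_per_m))
  } else {
    cat(sprintf("<tension_fit> not measurably flattened: gamma >= %.4g mN/m\n",
                x$gamma_lower_bound_mn_per_m))
  }
  print.shape_fit(x)
  invisible(x)
}

#' Tidy a tension fit
#'
#' @param x A `tension_fit`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per fitted quantity (`b`,
#'   `c`, `gamma`).  `glance()`: a one-row tibble of fit diagnostics.
#' @export
tidy.tension_fit <- function(x, ...) {
  tibble(
    term = c("b", "c", "gamma"),
    estimate = c(x$params$b, x$params$c, x$gamma_mn_per_m),
    unit = c("1/um", "1/um^2", "mN/m")
  )
}

#' @rdname tidy.tension_fit
#' @export
glance.tension_fit <- function(x, ...) {
  tibble(
    gamma_mn_per_m = x$gamma_mn_per_m,
    gamma_lower_bound_mn_per_m = x$gamma_lower_bound_mn_per_m,
    b_per_um = x$params$b,
    c_per_um2 = x$params$c,
    r_eq_um = x$r_eq,
    residual = x$residual,
    converged = x$converged,
    flattened = x$flattened,
    n_eval = x$n_eval
  )
}

#' Fit surface tension for every row of an observables table
#'
#' Maps [fit_tension()] over a tidy table of aggregate observables and
#' returns one row of [glance.tension_fit()] output per aggregate,
#' keeping any extra identifier columns (condition, replicate, ...).
#'
#' @param data A data frame with columns `h`, `w`, `v` (um, um, um^3)
#'   plus arbitrary identifier columns.
#' @param ctx A [magnetic_context()].
#' @param ... Passed on to [fit_shape()].
#' @return A tibble: the identifier columns followed by the glance
#'   columns of each fit.
#' @export
fit_tension_each <- function(data, ctx, ...) {
  if (!all(c("h", "w", "v") %in% names(data))) {
    abort_input("`data` must have columns h, w, v.")
  }
  ids <- data[setdiff(names(data), c("h", "w", "v"))]
  fits <- purrr::pmap(data[c("h", "w", "v")], function(h, w, v) {
    glance(fit_tension(list(h = h, w = w, v = v), ctx, ...))
  })
  dplyr::bind_cols(as_tibble(ids), dplyr::bind_rows(fits))
}
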