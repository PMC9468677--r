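#' Shape parameters of the flattened-spheroid profile
#'
#' The equilibrium profile of an axisymmetric aggregate flattened by a
#' uniform body force is fully determined by two parameters: the mean
#' curvature at the apex, `b`, and the capillary constant
#' `c = f / gamma`, the ratio of the body-force density to the surface
#' tension.  With lengths in micrometres, `b` has units 1/um and `c`
#' has units 1/um^2.  `c = 0` is the force-free limit (a sphere of
#' radius `1/b`); negative `c` is rejected.
#'
#' @param b Apex curvature (1/length), strictly positive.
#' @param c Capillary constant (1/length^2), non-negative.
#'
#' @return An object of class `shape_params`, a named list with fields
#'   `b` and `c`.
#' @examples
#' shape_params(b = 1, c = 0.5)
#' @export
shape_params <- function(b, c = 0) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    abort_input("`b` (apex curvature) must be a single finite value > 0.")
  }
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0) {
    abort_input("`c` (capillary constant) must be a single finite value >= 0.")
  }
  structure(list(b = as.numeric(b), c = as.numeric(c)), class = "shape_params")
}

#' @export
print.shape_params <- function(x, ...) {
  cat(sprintf("<shape_params> b = %g (1/L), c = %g (1/L^2)\n", x$b, x$c))
  invisible(x)
}

# right-hand side of the shape equation, parametrized by the inclination
# angle phi (the profile is convex for b > 0, c >= 0, so phi is a valid
# independent variable and termination at phi = pi is exact):
#   ds/dphi = 1 / g,   g = 2 b + c z - sin(phi) / x
#   dx/dphi = cos(phi) / g,  dz/dphi = sin(phi) / g
#   dV/dphi = pi x^2 sin(phi) / g
shape_rhs_phi <- function(phi, y, p) {
  # state y = (s, x, z, V).  Where the profile closes onto the axis
  # (x -> 0, only reached as c -> 0), the point is umbilic and
  # sin(phi)/x -> (2b + cz)/2.  Near that point the ratio divides two
  # vanishing quantities and amplifies the error carried by x, so the
  # analytic limit is substituted below x_eps; its own error there is
  # O(x_eps^2), well under the integration tolerance.
  sp <- sin(phi)
  x <- y[[2L]]
  ratio <- if (x > p$x_eps) sp / x else (2 * p$b + p$c * y[[3L]]) / 2
  g <- 2 * p$b + p$c * y[[3L]] - ratio
  list(c(1, cos(phi), sp, pi * x^2 * sp) / g)
}

# analytic first step away from the apex: the removable singularity
# sin(phi)/x -> b as s -> 0 is handled by the series x ~ s, z ~ b s^2/2,
# phi ~ b s, taken up to s0 = 1e-6 in apex-curvature units.
apex_series_state <- function(b, s0 = 1e-6 / b) {
  c(s = s0, x = s0, z = b * s0^2 / 2, V = pi * b * s0^4 / 4)
}

# The closure point phi = pi is singular in the sphere limit (x -> 0
# with sin(phi) -> 0), so the adaptive solver stops at pi - delta and
# the last sliver is covered by one explicit RK4 step (error O(delta^5),
# far below the integration tolerance).
closure_delta <- 1e-6

rk4_step <- function(phi, y, h, parms) {
  k1 <- shape_rhs_phi(phi, y, parms)[[1L]]
  k2 <- shape_rhs_phi(phi + h / 2, y + h / 2 * k1, parms)[[1L]]
  k3 <- shape_rhs_phi(phi + h / 2, y + h / 2 * k2, parms)[[1L]]
  k4 <- shape_rhs_phi(phi + h, y + h * k3, parms)[[1L]]
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

integrate_phi <- function(params, phis, rtol, atol, max_arc) {
  b <- params$b
  y0 <- apex_series_state(b)
  parms <- c(params, list(x_eps = 1e-4 / b))
  phis <- phis[phis < pi - closure_delta]
  phis <- c(phis, pi - closure_delta)
  out <- deSolve::lsodar(
    y = y0, times = phis, func = shape_rhs_phi,
    parms = parms, rtol = rtol, atol = atol,
    rootfunc = function(phi, y, p) y[[1L]] - max_arc,
    tcrit = max(phis),  # never step past the closure point
    maxsteps = 10000L
  )
  if (!is.null(attr(out, "troot")) && length(attr(out, "troot")) > 0) {
    abort_convergence(sprintf(
      "profile failed to close: arc length exceeded the guard %g before phi reached pi",
      max_arc
    ))
  }
  last <- out[nrow(out), ]
  y_end <- rk4_step(pi - closure_delta, last[-1L], closure_delta, parms)
  rbind(out, c(pi, y_end))
}

#' Integrate the axisymmetric Laplace shape equation
#'
#' Computes the equilibrium meridional profile of a non-wetting
#' axisymmetric drop subject to a uniform body force, by integrating
#'
#' \deqn{d\phi/ds = 2b + c z - \sin(\phi)/x,\quad dx/ds = \cos\phi,
#'   \quad dz/ds = \sin\phi}
#'
#' from the apex (`x = z = 0`, `phi = 0`, with the removable singularity
#' `sin(phi)/x -> b` handled by a series first step) until the profile
#' meets the non-adhesive substrate at `phi = pi` (contact angle 180
#' degrees).  The axial coordinate `z` increases from the apex towards
#' the substrate, i.e. in the direction of the body force.
#'
#' Internally the equation is integrated with `phi` as the independent
#' variable (the profile is convex for `c >= 0`, so `phi` increases
#' monotonically along the arc), which makes the terminal condition
#' exact and places the equator `phi = pi/2` on an output point.  The
#' enclosed volume is carried as an extra state, so the observables
#' returned by [compute_observables()] are accurate to the integrator
#' tolerance rather than to the output sampling.
#'
#' @param params A [shape_params()] object.
#' @param n_out Number of output samples along the profile.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param max_arc Guard arc length: if `phi` has not reached `pi` by
#'   this arc length the parameters are deemed pathological and a
#'   non-closure error is raised.  Default `50 / b`.
#'
#' @return A `profile_curve`: a tibble with columns `s` (arc length),
#'   `x` (radius), `z` (depth below the apex) and `phi` (inclination),
#'   starting at the apex row `(0, 0, 0, 0)` and ending at `phi = pi`.
#'   Attributes: `params`, `closed`, and `observables` (a list with the
#'   height `h`, width `w` and volume `V` computed during integration).
#' @examples
#' prof <- integrate_profile(shape_params(b = 1, c = 0))  # unit sphere
#' compute_observables(prof)
#' @export
integrate_profile <- function(params, n_out = 721L, rtol = 1e-9,
                              atol = 1e-12, max_arc = 50 / params$b) {
  stopifnot(inherits(params, "shape_params"))
  if (n_out < 5L) abort_input("`n_out` must be at least 5.")
  b <- params$b
  phi0 <- b * 1e-6 / b  # = 1e-6, series first step in apex units
  phis <- sort(unique(c(seq(phi0, pi, length.out = n_out), pi / 2)))
  out <- integrate_phi(params, phis, rtol, atol, max_arc)

  phi <- out[, 1L]
  s <- out[, "s"]
  x <- pmax(out[, "x"], 0)
  z <- pmax(out[, "z"], 0)
  v <- out[, "V"]
  i_eq <- which.min(abs(phi - pi / 2))
  obs <- list(h = z[[length(z)]], w = 2 * x[[i_eq]], v = v[[length(v)]])

  curve <- tibble(
    s = c(0, s), x = c(0, x), z = c(0, z), phi = c(0, phi)
  )
  structure(
    curve,
    params = params,
    closed = TRUE,
    observables = obs,
    class = c("profile_curve", class(curve))
  )
}

#' Fixed-step RK4 reference integration of the shape equation
#'
#' A deliberately simple fixed-step fourth-order Runge-Kutta
#' integration of the shape equation in its native arc-length form,
#' implemented in C++.  It serves as an independent reference for the
#' adaptive integrator: same equation, different parametrization,
#' different stepping scheme.  Termination at `phi = pi` is located by
#' linear interpolation inside the crossing step.
#'
#' @inheritParams integrate_profile
#' @param step Arc-length step (in the same length units as `1/b`).
#' @param thin Store every `thin`-th step in the returned curve (the
#'   terminal state is always appended exactly).
#' @return A `profile_curve` tibble (see [integrate_profile()]).
#' @export
integrate_profile_rk4 <- function(params, step = 1e-5, thin = 100L,
                                  max_arc = 50 / params$b) {
  stopifnot(inherits(params, "shape_params"))
  if (step <= 0) abort_input("`step` must be > 0.")
  res <- rk4_shape_cpp(params$b, params$c, step, 1e-6 / params$b,
                       max_arc, as.integer(thin))
  if (!res$closed) {
    abort_convergence(sprintf(
      "profile failed to close: arc length exceeded the guard %g before phi reached pi",
      max_arc
    ))
  }
  curve <- tibble(
    s = c(0, res$s), x = c(0, pmax(res$x, 0)),
    z = c(0, res$z), phi = c(0, res$phi)
  )
  structure(
    curve,
    params = params,
    closed = TRUE,
    observables = list(h = res$h, w = res$w, v = res$v),
    class = c("profile_curve", class(curve))
  )
}

is_closed_profile <- function(profile, tol = 1e-6) {
  abs(profile$phi[[nrow(profile)]] - pi) <= tol
}

# vertex of the parabola through three (u, y) points; falls back to the
# discrete maximum for degenerate geometry
quadratic_peak <- function(u, y) {
  d21 <- u[2L] - u[1L]; d31 <- u[3L] - u[1L]; d32 <- u[3L] - u[2L]
  denom <- d21 * d31 * d32
  if (denom == 0) return(max(y))
  a <- (y[3L] * d21 - y[2L] * d31 + y[1L] * d32) / denom
  if (a >= 0) return(max(y))
  bb <- (y[2L] - y[1L]) / d21 - a * (u[1L] + u[2L])
  u_star <- -bb / (2 * a)
  cc <- y[1L] - a * u[1L]^2 - bb * u[1L]
  a * u_star^2 + bb * u_star + cc
}

#' Geometric observables of a closed profile
#'
#' Reduces a profile to the three quantities the inverse fit uses:
#' height `h` (depth of the contact plane below the apex), width `w`
#' (equatorial diameter, twice the maximal radius) and volume `V` of
#' the solid of revolution, `V = pi * integral of x^2 sin(phi) ds`
#' (the flat contact disk closes the solid).
#'
#' Profiles produced by [integrate_profile()] or
#' [integrate_profile_rk4()] carry integrator-accurate observables and
#' these are returned directly.  For externally supplied curves the
#' observables are recomputed from the samples: `h` from the terminal
#' `z`, `w` from a local parabolic refinement of the sampled maximum of
#' `x`, and `V` by trapezoidal quadrature.
#'
#' @param profile A `profile_curve` reaching `phi = pi`.
#' @param tol Closure tolerance on the terminal `phi`.
#' @return A one-row tibble with columns `h`, `w`, `v`.
#' @export
compute_observables <- function(profile, tol = 1e-6) {
  if (!is.data.frame(profile) ||
      !all(c("s", "x", "z", "phi") %in% names(profile))) {
    abort_input("`profile` must have columns s, x, z, phi.")
  }
  if (!is_closed_profile(profile, tol)) {
    abort_input("profile is not closed: terminal phi has not reached pi.")
  }
  obs <- attr(profile, "observables")
  if (is.null(obs)) {
    n <- nrow(profile)
    i <- which.max(profile$x)
    idx <- if (i <= 1L) 1:3 else if (i >= n) (n - 2L):n else (i - 1L):(i + 1L)
    w <- 2 * quadratic_peak(profile$s[idx], profile$x[idx])
    v <- pi * pracma::trapz(profile$s, profile$x^2 * sin(profile$phi))
    obs <- list(h = profile$z[[n]], w = w, v = v)
  }
  tibble(h = obs$h, w = obs$w, v = obs$v)
}

# fast forward map used by the inverse fit: observables only, three
# output points (apex, equator, contact), integrator-exact h, w, V
forward_observables <- function(b, c, rtol = 1e-9, atol = 1e-12,
                                max_arc = 50 / b) {
  params <- shape_params(b, c)
  phis <- c(1e-6, pi / 2, pi)
  out <- integrate_phi(params, phis, rtol, atol, max_arc)
  n <- nrow(out)
  c(h = out[[n, "z"]], w = 2 * out[[2L, "x"]], v = out[[n, "V"]])
}

#' Rescale shape parameters to and from dimensionless form
#'
#' Fitting is carried out in units of a reference length `R` (by
#' convention the equivalent radius `R_eq = (3V / 4 pi)^(1/3)`):
#' `b_scaled = b * R`, `c_scaled = c * R^2`.  `redimensionalize()` is
#' the exact inverse.
#'
#' @param params A [shape_params()] object.
#' @param length_scale Reference length `R > 0`.
#' @return A [shape_params()] object in the new units.
#' @examples
#' nondimensionalize(shape_params(0.01, 4e-6), 100)  # b = 1, c = 0.04
#' @export
nondimensionalize <- function(params, length_scale) {
  stopifnot(inherits(params, "shape_params"))
  if (!is.numeric(length_scale) || length(length_scale) != 1L ||
      !is.finite(length_scale) || length_scale <= 0) {
    abort_input("`length_scale` must be a single finite value > 0.")
  }
  shape_params(params$b * length_scale, params$c * length_scale^2)
}

#' @rdname nondimensionalize
#' @export
redimensionalize <- function(params, length_scale) {
  stopifnot(inherits(params, "shape_params"))
  if (!is.numeric(length_scale) || length(length_scale) != 1L ||
      !is.finite(length_scale) || length_scale <= 0) {
    abort_input("`length_scale` must be a single finite value > 0.")
  }
  shape_params(params$b / length_scale, params$c / length_scale^2)
}

#' Equivalent spherical radius of a volume
#'
#' @param v Volume (length^3).
#' @return `(3 v / 4 pi)^(1/3)`.
#' @export
equivalent_radius <- function(v) {
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort_input("volume must be finite and > 0.")
  }
  (3 * v / (4 * pi))^(1 / 3)
}
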