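# Independent oracles used by the tests.  They deliberately share no
# code with the implementation paths they check.

# two-sided Mann-Whitney p by full enumeration of rank assignments
enum_mann_whitney_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(ix) sum(seq_len(n)[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# trapezoidal solid-of-revolution volume from profile samples
trapz_volume <- function(profile) {
  pi * pracma::trapz(profile$s, profile$x^2 * sin(profile$phi))
}

# forward observables at a parameter pair, as a plain named list
forward_obs_list <- function(b, c) {
  o <- compute_observables(integrate_profile(shape_params(b, c)))
  list(h = o$h, w = o$w, v = o$v)
}

# apex curvature that closes the scaled volume 4*pi/3 at a given scaled c
b_for_unit_volume <- function(c_scaled) {
  uniroot(
    function(b) compute_observables(integrate_profile(shape_params(b, c_scaled)))$v - 4 * pi / 3,
    c(0.05, 5), extendInt = "downX", tol = 1e-9
  )$root
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
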