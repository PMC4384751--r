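# Independent oracles used across the suite. These never call the closed
# forms they are checking.

# Mean of F ~ N(I - mu*T, (sigma*T)^2) truncated to [0, I], by quadrature in
# the standardized variable. The window is clipped to 40 SD around the
# density maximum inside the truncation interval; the neglected mass is far
# below double precision.
quad_expected_fret <- function(I, T_ab, mu, sigma) {
  a <- I - mu * T_ab
  s <- sigma * T_ab
  alpha <- -a / s
  beta <- (I - a) / s
  z0 <- min(max(0, alpha), beta)
  lo <- max(alpha, z0 - 40)
  hi <- min(beta, z0 + 40)
  w <- function(z) exp(-(z^2 - z0^2) / 2)
  num <- stats::integrate(function(z) (a + s * z) * w(z), lo, hi,
                          rel.tol = 1e-10, abs.tol = 0)$value
  den <- stats::integrate(w, lo, hi, rel.tol = 1e-10, abs.tol = 0)$value
  num / den
}

# Mean of the jointly [0, I]-truncated mixture of F-scale Gaussians, by
# piecewise quadrature with breakpoints at each component's 40-SD window.
quad_expected_fret_mixture <- function(I, T_ab, mix) {
  dens <- function(F) {
    d <- 0
    for (i in seq_along(mix$weights))
      d <- d + mix$weights[i] *
        stats::dnorm(F, I - mix$means[i] * T_ab, mix$sds[i] * T_ab)
    d
  }
  brk <- c(0, I, as.vector(vapply(seq_along(mix$weights), function(i) {
    m <- I - mix$means[i] * T_ab
    s <- mix$sds[i] * T_ab
    c(m - 40 * s, m + 40 * s)
  }, numeric(2))))
  brk <- sort(unique(pmin(pmax(brk, 0), I)))
  num <- den <- 0
  for (k in seq_len(length(brk) - 1)) {
    if (brk[k + 1] - brk[k] <= 0) next
    num <- num + stats::integrate(function(F) F * dens(F), brk[k], brk[k + 1],
                                  rel.tol = 1e-10, abs.tol = 1e-300)$value
    den <- den + stats::integrate(dens, brk[k], brk[k + 1],
                                  rel.tol = 1e-10, abs.tol = 1e-300)$value
  }
  num / den
}

# Closed-form logistic solution of dN/dt = f*N - rho*N^2.
logistic_npe <- function(t, N0, f, rho) {
  K <- f / rho
  K / (1 + (K / N0 - 1) * exp(-f * t))
}

# Area of the lens of two intersecting discs (independent re-derivation for
# the colocalization boundary test).
disc_lens_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
    r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
    0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
}

# Reference parameters with overrides, bypassing none of the validation.
params_with_overrides <- function(...) {
  do.call(model_params, utils::modifyList(unclass(reference_params()),
                                          list(...)))
}
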