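# Spectral bleed-through correction for FRET-channel intensities.
#
# The bleed-through ratio m = (I - F)/T (FRET-channel signal not due to
# energy transfer, per unit of acceptor-antibody signal T) is modelled as a
# Gaussian or two-component Gaussian mixture estimated on control objects.
# Given measured (I, T), the corrected intensity is the expectation of F
# under that ratio model, truncated to the physically admissible range
# 0 <= F <= I.

#' Construct a Gaussian mixture model for the bleed-through ratio
#'
#' Holds the component weights, means and standard deviations of the
#' distribution of per-object intensity ratios m = I/T measured on
#' bleed-through control objects (objects whose FRET-channel signal is pure
#' crosstalk). Components are stored sorted by increasing mean.
#'
#' @param weights Numeric vector of component weights; must sum to 1.
#' @param means Numeric vector of component means (dimensionless ratios).
#' @param sds Numeric vector of component standard deviations, all `> 0`.
#' @return An object of class `ratio_mixture`.
#' @examples
#' ratio_mixture(c(0.7, 0.3), c(0.8, 2.0), c(0.2, 0.5))
#' @export
ratio_mixture <- function(weights, means, sds) {
  stopifnot(length(weights) == length(means), length(means) == length(sds))
  if (abs(sum(weights) - 1) > 1e-9)
    stop("mixture weights must sum to 1 (got ", sum(weights), ")")
  if (any(weights < 0)) stop("mixture weights must be non-negative")
  if (any(sds <= 0)) stop("mixture standard deviations must be > 0")
  ord <- order(means)
  structure(
    list(weights = weights[ord], means = means[ord], sds = sds[ord]),
    class = "ratio_mixture"
  )
}

#' @export
print.ratio_mixture <- function(x, ...) {
  cat("Bleed-through ratio mixture (", length(x$weights), " component",
      if (length(x$weights) > 1) "s", "):\n", sep = "")
  for (i in seq_along(x$weights))
    cat(sprintf("  a=%.4f  mu=%.4f  sigma=%.4f\n",
                x$weights[i], x$means[i], x$sds[i]))
  invisible(x)
}

#' Mixture density of the bleed-through ratio
#'
#' @param m Ratio values at which to evaluate the density.
#' @param mixture A [ratio_mixture()].
#' @return Density values.
#' @export
dratio_mixture <- function(m, mixture) {
  stopifnot(inherits(mixture, "ratio_mixture"))
  d <- 0
  for (i in seq_along(mixture$weights))
    d <- d + mixture$weights[i] * stats::dnorm(m, mixture$means[i], mixture$sds[i])
  d
}

#' Classical linear bleed-through correction
#'
#' Subtracts the mean bleed-through coefficient times the acceptor-channel
#' intensity: `F = I - k * T`. Applied per endosome this can (and for broad
#' ratio distributions frequently does) return negative intensities, which
#' motivates the probabilistic correction [expected_fret()].
#'
#' @param I Raw FRET-channel integral intensity (a.u.).
#' @param T_ab Acceptor (anti-phosphotyrosine antibody) channel intensity (a.u.).
#' @param k Bleed-through coefficient, the ratio of control-object means; `>= 0`.
#' @return Corrected intensity `I - k * T_ab`; may be negative.
#' @examples
#' gordon_correction(100, 50, 1.0) # 50
#' gordon_correction(10, 20, 1.0)  # -10
#' @export
gordon_correction <- function(I, T_ab, k) {
  if (any(k < 0)) stop("bleed-through coefficient k must be >= 0")
  I - k * T_ab
}

# Mean of a normal(mean = m, sd = s) truncated to [0, I], computed stably.
# Returns s * ((phi(alpha) - phi(beta)) / Z - alpha) rather than
# m + s * ratio to avoid catastrophic cancellation deep in the tail.
trunc_norm_mean_01 <- function(I, m, s) {
  alpha <- (0 - m) / s
  beta <- (I - m) / s
  # Z = Phi(beta) - Phi(alpha), via whichever tail is better conditioned
  if (alpha >= 0) {
    # both bounds in the upper tail: work with survival functions
    la <- stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE)
    lb <- stats::pnorm(beta, lower.tail = FALSE, log.p = TRUE)
    if (!(lb < la))  # tail masses indistinguishable at double precision
      return(trunc_mean_quad(I, m, s))
    lZ <- la + log1p(-exp(lb - la))
    lphi_a <- stats::dnorm(alpha, log = TRUE)
    lphi_b <- stats::dnorm(beta, log = TRUE)
    ratio <- exp(lphi_a - lZ) - exp(lphi_b - lZ)
  } else if (beta <= 0) {
    la <- stats::pnorm(alpha, log.p = TRUE)
    lb <- stats::pnorm(beta, log.p = TRUE)
    if (!(la < lb))
      return(trunc_mean_quad(I, m, s))
    lZ <- lb + log1p(-exp(la - lb))
    ratio <- exp(stats::dnorm(alpha, log = TRUE) - lZ) -
      exp(stats::dnorm(beta, log = TRUE) - lZ)
  } else {
    Z <- stats::pnorm(beta) - stats::pnorm(alpha)
    ratio <- (stats::dnorm(alpha) - stats::dnorm(beta)) / Z
  }
  out <- s * (ratio - alpha)
  # mean = m + s * ratio = s * (ratio - alpha); the latter is stable when
  # m is large and negative (mean pinned just above 0)
  if (!is.finite(out) || out < 0 || out > I) trunc_mean_quad(I, m, s) else out
}

# Quadrature fallback for truncation windows so deep in a tail that the
# closed form loses all precision: integrate in the standardized variable
# with the exponential weight rescaled to the window's density maximum.
trunc_mean_quad <- function(I, m, s) {
  alpha <- (0 - m) / s
  beta <- (I - m) / s
  z0 <- min(max(0, alpha), beta)
  lo <- max(alpha, z0 - 40)
  hi <- min(beta, z0 + 40)
  w <- function(z) exp(-(z^2 - z0^2) / 2)
  num <- stats::integrate(function(z) (z - alpha) * w(z), lo, hi,
                          rel.tol = 1e-10, abs.tol = 0)$value
  den <- stats::integrate(w, lo, hi, rel.tol = 1e-10, abs.tol = 0)$value
  s * num / den
}

# Normalization mass Z = P(0 <= F <= I) for the same truncated normal.
trunc_norm_mass_01 <- function(I, m, s) {
  alpha <- (0 - m) / s
  beta <- (I - m) / s
  stats::pnorm(beta) - stats::pnorm(alpha)
}

#' Expected FRET intensity under a single-Gaussian bleed-through model
#'
#' The bleed-through ratio m = (I - F)/T is modelled as N(mu, sigma^2), so F
#' is normal with mean `I - mu * T_ab` and SD `sigma * T_ab`. Because the
#' bleed-through cannot exceed the measured intensity (0 <= F <= I), the
#' corrected value is the mean of that normal truncated to `[0, I]`:
#' always strictly positive and at most `I`, even when `I - mu * T_ab < 0`.
#'
#' The default (`method = "exact"`) evaluates the truncated-normal mean in
#' closed form; for `I - mu * T_ab >= 0` it coincides with the published
#' sign-split formula, which is retained as `method = "as-printed"`.
#'
#' @param I Raw FRET-channel intensity (a.u.), `>= 0`. Vectorized.
#' @param T_ab Acceptor-channel intensity (a.u.), `>= 0`. Objects with
#'   `T_ab = 0` cannot contain bleed-through and return `I` unchanged.
#' @param mu,sigma Mean and SD of the bleed-through ratio; `sigma > 0`.
#' @param method `"exact"` (default) or `"as-printed"`.
#' @return Expected corrected intensity, in `(0, I]`.
#' @examples
#' expected_fret(100, 50, 1.2, 1e-6) # ~ 40, the linear correction
#' expected_fret(10, 50, 1.0, 0.5)   # positive despite I - mu*T < 0
#' @export
expected_fret <- function(I, T_ab, mu, sigma, method = c("exact", "as-printed")) {
  method <- match.arg(method)
  if (any(sigma <= 0)) stop("sigma must be > 0")
  n <- max(length(I), length(T_ab), length(mu), length(sigma))
  I <- rep_len(I, n); T_ab <- rep_len(T_ab, n)
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  out <- numeric(n)
  for (j in seq_len(n)) {
    if (T_ab[j] == 0) { out[j] <- I[j]; next }  # no bleed-through possible
    m <- I[j] - mu[j] * T_ab[j]
    s <- sigma[j] * T_ab[j]
    if (method == "exact") {
      out[j] <- trunc_norm_mean_01(I[j], m, s)
    } else {
      A <- 0.5 * (m / s)^2
      B <- 0.5 * (mu[j] / sigma[j])^2
      num <- (1 - exp(-B)) - sign(m) * (1 - exp(-A))
      den <- erf(mu[j] / (sqrt(2) * sigma[j])) + erf(m / (sqrt(2) * s))
      out[j] <- m + sqrt(2 / pi) * s * num / den
    }
  }
  out
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Expected FRET intensity under a two-component mixture bleed-through model
#'
#' Generalizes [expected_fret()] to a bleed-through ratio distributed as a
#' two-component Gaussian mixture. Under the mixture, F = I - m * T is a
#' mixture of Gaussians; the default returns the exact mean of that mixture
#' truncated jointly to `[0, I]`, computed in closed form per component:
#' \deqn{\langle F\rangle = \frac{\sum_i a_i Z_i m_i^{tr}}{\sum_i a_i Z_i}}
#' where \eqn{Z_i} is component i's mass on `[0, I]` and \eqn{m_i^{tr}} its
#' truncated mean. Components with zero weight are dropped before the
#' computation, so a degenerate mixture reduces exactly to the
#' single-component estimator.
#'
#' `method = "restored"` and `method = "as-printed"` give the published
#' single-formula approximations built from effective moments
#' (`M`, `N` intermediates), with and without the dimensional repair
#' `erf(sqrt(M))`, `e^{-M}`; they are provided for comparison and are not
#' exact for well-separated components.
#'
#' @param I,T_ab Intensities as in [expected_fret()]. Vectorized.
#' @param mixture A [ratio_mixture()] with 1 or 2 components of positive
#'   weight (more active components are not supported).
#' @param method `"exact"` (default), `"restored"`, or `"as-printed"`.
#' @return Expected corrected intensity, in `(0, I]`.
#' @export
expected_fret_mixture <- function(I, T_ab, mixture,
                                  method = c("exact", "restored", "as-printed")) {
  method <- match.arg(method)
  stopifnot(inherits(mixture, "ratio_mixture"))
  active <- mixture$weights > 0
  if (sum(active) > 2)
    stop("unsupported model: more than 2 active mixture components")
  a <- mixture$weights[active]
  a <- a / sum(a)
  mus <- mixture$means[active]
  sigs <- mixture$sds[active]
  if (length(a) == 1 && method == "exact")
    return(expected_fret(I, T_ab, mus, sigs))
  n <- max(length(I), length(T_ab))
  I <- rep_len(I, n); T_ab <- rep_len(T_ab, n)
  out <- numeric(n)
  if (method == "exact") {
    for (j in seq_len(n)) {
      if (T_ab[j] == 0) { out[j] <- I[j]; next }
      num <- den <- 0
      for (i in seq_along(a)) {
        m <- I[j] - mus[i] * T_ab[j]
        s <- sigs[i] * T_ab[j]
        Z <- trunc_norm_mass_01(I[j], m, s)
        if (Z > 0) {
          num <- num + a[i] * Z * trunc_norm_mean_01(I[j], m, s)
          den <- den + a[i] * Z
        }
      }
      out[j] <- if (den > 0) num / den else {
        # all component mass outside [0, I]: fall back to the dominant
        # component's truncated mean (mass cancels in the ratio limit)
        i <- which.max(a)
        trunc_norm_mean_01(I[j], I[j] - mus[i] * T_ab[j], sigs[i] * T_ab[j])
      }
    }
    return(out)
  }
  # published single-formula variants, effective moments over active components
  mu_bar <- sum(a * mus)
  s2_bar <- sum(a^2 * sigs^2)
  M <- sum((mus / (sqrt(2) * sigs))^2)
  for (j in seq_len(n)) {
    if (T_ab[j] == 0) { out[j] <- I[j]; next }
    sT <- sqrt(s2_bar) * T_ab[j]
    Nj <- (I[j] - mu_bar * T_ab[j]) / (sqrt(2) * sT)
    num <- (1 - exp(-M)) - sign(Nj) * (1 - exp(-Nj^2))
    den <- if (method == "restored") erf(sqrt(M)) + erf(Nj) else erf(M) + erf(Nj)
    out[j] <- (I[j] - mu_bar * T_ab[j]) + sqrt(2 / pi) * sT * num / den
  }
  out
}

#' Fit a Gaussian mixture to control-object intensity ratios
#'
#' Maximum-likelihood (EM) fit of a `K`-component univariate Gaussian
#' mixture with unequal variances to the sample of ratios m = I/T measured
#' on bleed-through control objects. When `K = 3` the two lowest-mean
#' components are flagged as bleed-through (the third absorbs genuine FRET
#' or outlier objects) and the returned correction mixture contains only
#' those two, with weights renormalized.
#'
#' @param ratios Numeric vector of per-object intensity ratios; at least 50
#'   finite values are required. Ratios whose acceptor intensity fell below
#'   a floor should be excluded beforehand (see `t_floor` in
#'   [correct_object_table()]).
#' @param K Number of components, 1, 2 or 3.
#' @return A list with elements `mixture` (the [ratio_mixture()] to use for
#'   correction), `full` (all `K` fitted components as a data.frame),
#'   `loglik`, and `bleedthrough_components` (indices into `full`).
#' @export
fit_ratio_mixture <- function(ratios, K = 2) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 50)
    stop("need at least 50 finite ratios, got ", length(ratios))
  if (!K %in% 1:3) stop("K must be 1, 2 or 3")
  if (stats::sd(ratios) < .Machine$double.eps^0.5 * max(1, abs(mean(ratios))))
    stop("degenerate sample: ratios have (near-)zero variance")
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  fit <- mclust::Mclust(ratios, G = K, modelNames = if (K == 1) "X" else "V",
                        verbose = FALSE)
  if (is.null(fit))
    stop("mixture fit did not converge; inspect the ratio sample")
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  sig <- rep_len(sig, K)  # mclust collapses equal variances
  w <- as.numeric(fit$parameters$pro)
  if (is.null(w)) w <- 1
  ord <- order(mu)
  mu <- mu[ord]; sig <- sig[ord]; w <- w[ord]
  full <- data.frame(weight = w, mean = mu, sd = sig)
  bt <- if (K == 3) 1:2 else seq_len(K)
  wbt <- w[bt] / sum(w[bt])
  list(
    mixture = ratio_mixture(wbt, mu[bt], sig[bt]),
    full = full,
    loglik = fit$loglik,
    bleedthrough_components = bt
  )
}

#' Apply the mixture bleed-through correction to an endosome object table
#'
#' Adds a column `F_corrected` with the per-row expected FRET intensity
#' given the raw FRET-channel (`I_fret`) and acceptor-channel (`I_ptyr`)
#' intensities. Rows with zero acceptor intensity are returned unchanged
#' (`F_corrected = I_fret`).
#'
#' @param records A data.frame with columns `I_fret` and `I_ptyr` (see
#'   [generate_endosome_table()] for the canonical layout).
#' @param mixture A [ratio_mixture()] (or the list returned by
#'   [fit_ratio_mixture()], whose `$mixture` element is then used).
#' @return `records` with an added/overwritten `F_corrected` column; the
#'   row count is preserved.
#' @export
correct_object_table <- function(records, mixture) {
  if (inherits(mixture, "list") && !is.null(mixture$mixture))
    mixture <- mixture$mixture
  need <- c("I_fret", "I_ptyr")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("object table is missing required columns: ",
         paste(miss, collapse = ", "))
  records$F_corrected <- if (nrow(records) == 0) numeric(0) else
    expected_fret_mixture(records$I_fret, records$I_ptyr, mixture)
  records
}
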