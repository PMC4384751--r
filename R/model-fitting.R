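# Multi-dose weighted least-squares fitting of the trafficking model.
#
# Observables are measured in arbitrary intensity units, so each observable
# is compared to the model through an analytic scale factor — the exact
# weighted-least-squares minimizer of sum(((d - c*s)/sigma)^2) over c —
# shared across doses (one microscope calibration per observable).

#' Analytic weighted least-squares scale factor
#'
#' `scale = sum(d * s / sigma^2) / sum(s^2 / sigma^2)`: the exact minimizer
#' of the weighted residual sum of squares between data `d` and scaled model
#' predictions `c * s`.
#'
#' @param d Data values.
#' @param s Model predictions, same length; not all zero.
#' @param sigma SEMs, `> 0`, recycled.
#' @return The scale factor.
#' @examples
#' scale_factor(c(2, 4, 6), c(1, 2, 3), 1) # 2
#' @export
scale_factor <- function(d, s, sigma) {
  stopifnot(length(d) == length(s))
  sigma <- rep_len(sigma, length(d))
  if (any(sigma <= 0)) stop("sigma must be > 0")
  den <- sum(s^2 / sigma^2)
  if (den == 0) stop("all model values are zero: scale factor undefined")
  sum(d * s / sigma^2) / den
}

#' Define a model-fitting problem
#'
#' @param data Long time-course table with columns `dose, observable, time,
#'   value, sem` (the layout of [generate_timecourse_data()]).
#' @param free Character vector of free parameter names (subset of
#'   [model_params()] fields). Default: the identifiable quintet
#'   `beta2, Q, rho, k_in, s_v`.
#' @param fixed A [model_params()] supplying every non-free parameter (and
#'   the starting point scale).
#' @param lower,upper Named bounds for the free parameters (positive).
#' @param n_starts Number of Latin-hypercube multi-start points.
#' @param seed Integer seed for the starts.
#' @param variant `"sigmoidal"` (full model) or `"first-order"`
#'   (`beta1 = beta2`, constant dephosphorylation).
#' @param shared_scale Share each observable's scale factor across doses
#'   (default) or estimate per dose.
#' @param absolute_observables Observables measured in absolute units whose
#'   scale is fixed at 1. Default `"n_pe"`: endosome numbers are densities
#'   per 1000 um^2, not arbitrary intensity units, and anchoring them also
#'   removes the joint rescaling degeneracy of `(s_v, Q, rho)`.
#' @return List of class `fit_problem`.
#' @export
fit_problem <- function(data, free = c("beta2", "Q", "rho", "k_in", "s_v"),
                        fixed = reference_params(),
                        lower = NULL, upper = NULL,
                        n_starts = 8L, seed = 1L,
                        variant = c("sigmoidal", "first-order"),
                        shared_scale = TRUE,
                        absolute_observables = "n_pe") {
  variant <- match.arg(variant)
  need <- c("dose", "observable", "time", "value", "sem")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data is missing columns: ", paste(miss, collapse = ", "))
  obs_known <- c("n_pe", "s_pe", "s_pe_per_endosome", "s_vesicular")
  unknown <- setdiff(unique(data$observable), obs_known)
  if (length(unknown))
    stop("unknown observable(s): ", paste(unknown, collapse = ", "))
  if (!all(free %in% names(fixed))) stop("free parameters must name model parameters")
  ref <- unlist(fixed[free])
  if (is.null(lower)) lower <- ref / 20
  if (is.null(upper)) upper <- ref * 20
  structure(list(data = data, free = free, fixed = fixed,
                 lower = lower[free], upper = upper[free],
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 variant = variant, shared_scale = shared_scale,
                 absolute_observables = absolute_observables),
            class = "fit_problem")
}

params_with <- function(fixed, free_names, values, variant) {
  p <- fixed
  p[free_names] <- as.list(values)
  if (variant == "first-order") p$beta1 <- p$beta2
  class(p) <- "model_params"
  p
}

# Weighted residual vector (d - scale*s)/sigma over all points of a problem
# for a candidate free-parameter vector; simulation failures give a flat
# penalty vector so the optimizer backs away.
problem_residuals <- function(values, problem, rtol = 1e-6, atol = 1e-8) {
  dat <- problem$data
  p <- try(params_with(problem$fixed, problem$free, values, problem$variant),
           silent = TRUE)
  if (inherits(p, "try-error"))
    return(structure(rep(1e6, nrow(dat)), failed = TRUE))
  dat$model <- NA_real_
  for (dose in unique(dat$dose)) {
    sel <- dat$dose == dose
    times <- sort(unique(dat$time[sel]))
    sim <- try(simulate_model(p, stimulus(dose), times, rtol = rtol, atol = atol),
               silent = TRUE)
    if (inherits(sim, "try-error"))
      return(structure(rep(1e6, nrow(dat)), failed = TRUE))
    obs <- sim$observables
    for (nm in unique(dat$observable[sel])) {
      s2 <- sel & dat$observable == nm
      dat$model[s2] <- obs[[nm]][match(dat$time[s2], obs$time)]
    }
  }
  res <- numeric(nrow(dat))
  grp <- if (problem$shared_scale) dat$observable
         else interaction(dat$observable, dat$dose)
  abso <- problem$absolute_observables
  for (g in unique(grp)) {
    s3 <- grp == g
    sc <- if (dat$observable[which(s3)[1]] %in% abso) 1
          else if (all(dat$model[s3] == 0)) 0
          else scale_factor(dat$value[s3], dat$model[s3], dat$sem[s3])
    res[s3] <- (dat$value[s3] - sc * dat$model[s3]) / dat$sem[s3]
  }
  res
}

#' Weighted sum-of-squares objective
#'
#' Simulates the model at every dose in the problem, rescales each
#' observable by its analytic [scale_factor()], and returns
#' `sum(((d - scale*s)/sem)^2)`. Simulation failures return a large
#' penalized value with attribute `failed = TRUE`.
#'
#' @param values Named (or problem-ordered) free-parameter values.
#' @param problem A [fit_problem()].
#' @return Weighted SSR (attribute `failed` when penalized).
#' @export
objective <- function(values, problem) {
  stopifnot(inherits(problem, "fit_problem"))
  # reference tolerances here (fit_model relaxes them internally for speed)
  r <- problem_residuals(values, problem, rtol = 1e-8, atol = 1e-10)
  structure(sum(r^2), failed = isTRUE(attr(r, "failed")))
}

#' Fit the trafficking model to multi-dose time courses
#'
#' Bounded Levenberg-Marquardt least squares over log-transformed free
#' parameters with Latin-hypercube multi-start. The best start is returned
#' together with every restart's SSR.
#'
#' @param problem A [fit_problem()].
#' @return List of class `fit_result`: `params` (full [model_params()]),
#'   `free_values`, `ssr`, `scale_factors` (per observable),
#'   `restart_ssr`, `at_bound` (logical per free parameter), `convergence`.
#' @export
fit_model <- function(problem) {
  stopifnot(inherits(problem, "fit_problem"))
  k <- length(problem$free)
  llo <- log(problem$lower); lhi <- log(problem$upper)
  set.seed(problem$seed)
  # Latin hypercube over log-bounds; first start at the mid-point
  n <- problem$n_starts
  u <- matrix(stats::runif(n * k), n, k)
  for (j in seq_len(k)) u[, j] <- (sample.int(n) - u[, j]) / n
  starts <- rbind((llo + lhi) / 2,
                  sweep(sweep(u, 2, lhi - llo, `*`), 2, llo, `+`))
  best <- NULL
  restart_ssr <- numeric(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[i, ],
      lower = llo, upper = lhi,
      fn = function(lp) problem_residuals(exp(lp), problem),
      control = minpack.lm::nls.lm.control(maxiter = 150, ptol = 1e-10,
                                           ftol = 1e-10)), silent = TRUE)
    if (inherits(fit, "try-error")) { restart_ssr[i] <- NA; next }
    ssr <- sum(fit$fvec^2)
    restart_ssr[i] <- ssr
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) stop("no restart converged; restart SSRs: ",
                          paste(signif(restart_ssr, 4), collapse = ", "))
  lp <- best$fit$par
  vals <- stats::setNames(exp(lp), problem$free)
  pfit <- params_with(problem$fixed, problem$free, vals, problem$variant)
  # per-observable scale factors at the optimum (fine tolerance)
  dat <- problem$data
  dat$model <- NA_real_
  scales <- list()
  for (dose in unique(dat$dose)) {
    sel <- dat$dose == dose
    times <- sort(unique(dat$time[sel]))
    obs <- simulate_model(pfit, stimulus(dose), times)$observables
    for (nm in unique(dat$observable[sel])) {
      s2 <- sel & dat$observable == nm
      dat$model[s2] <- obs[[nm]][match(dat$time[s2], obs$time)]
    }
  }
  for (nm in unique(dat$observable))
    scales[[nm]] <- if (nm %in% problem$absolute_observables) 1
      else scale_factor(dat$value[dat$observable == nm],
                        dat$model[dat$observable == nm],
                        dat$sem[dat$observable == nm])
  tol_bound <- 1e-3
  at_bound <- (lp - llo < tol_bound) | (lhi - lp < tol_bound)
  structure(list(params = pfit, free_values = vals, ssr = best$ssr,
                 scale_factors = unlist(scales),
                 restart_ssr = restart_ssr,
                 at_bound = stats::setNames(at_bound, problem$free),
                 convergence = best$fit$info),
            class = "fit_result")
}

#' Steady-state per-endosome plateau metric
#'
#' Ratio of the maximum to the minimum steady (end-of-window) mean p-EGFR
#' per endosome across EGF doses. A value near 1 indicates the dose plateau
#' characteristic of the sigmoidal dephosphorylation model; the first-order
#' variant grows steeply with dose.
#'
#' @param params A [model_params()].
#' @param doses EGF doses (ng/ml).
#' @param t_eval Evaluation time (min); default 60, the end of the fitted
#'   window.
#' @param variant `"sigmoidal"` or `"first-order"`.
#' @return List with `fold` (max/min) and `per_dose` values.
#' @export
plateau_metric <- function(params, doses = c(0.5, 1, 5, 10), t_eval = 60,
                           variant = c("sigmoidal", "first-order")) {
  variant <- match.arg(variant)
  times <- seq(0, t_eval, by = 1)
  vals <- vapply(doses, function(d) {
    sim <- if (variant == "sigmoidal")
      simulate_model(params, stimulus(d), times)
    else simulate_first_order(params, stimulus(d), times)
    sim$observables$s_pe_per_endosome[length(times)]
  }, numeric(1))
  list(fold = max(vals) / min(vals), per_dose = stats::setNames(vals, doses))
}

#' Fit and compare the sigmoidal and first-order model variants
#'
#' Fits both dephosphorylation variants to the same multi-dose data and
#' reports, per variant, the total weighted SSR, the SSR restricted to each
#' observable, and the steady-state plateau metric of the fitted parameters.
#'
#' @param problem A [fit_problem()]; its `variant` field is overridden.
#' @return List with elements `sigmoidal` and `first_order`, each holding
#'   `fit`, `ssr_per_observable`, `plateau`; and `preferred`, the variant
#'   with the lower SSR on the mean-per-endosome observable.
#' @export
compare_models <- function(problem) {
  out <- list()
  for (v in c("sigmoidal", "first-order")) {
    pb <- problem
    pb$variant <- v
    class(pb) <- "fit_problem"
    fit <- fit_model(pb)
    res <- problem_residuals(fit$free_values, pb)
    ssr_obs <- tapply(res^2, pb$data$observable, sum)
    pl <- plateau_metric(fit$params, unique(pb$data$dose),
                         max(pb$data$time),
                         if (v == "sigmoidal") "sigmoidal" else "first-order")
    out[[if (v == "sigmoidal") "sigmoidal" else "first_order"]] <-
      list(fit = fit, ssr_per_observable = ssr_obs, plateau = pl)
  }
  key <- "s_pe_per_endosome"
  out$preferred <- if (out$sigmoidal$ssr_per_observable[key] <=
                       out$first_order$ssr_per_observable[key])
    "sigmoidal" else "first-order"
  out
}
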