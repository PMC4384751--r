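# Six-state kinetic model of p-EGFR propagation through the endosomal
# network. States: non-phosphorylated and phosphorylated EGFR at the plasma
# membrane (S_m, S_mp), non-phosphorylated and phosphorylated EGFR in early
# endosomes (S_e, S_pe), EGFR in recycling endosomes (S_re), and the number
# of p-EGFR-positive early endosomes (N_pe). The dephosphorylation rate in
# early endosomes depends sigmoidally on the p-EGFR load per endosome
# (S_pe / N_pe), which is what buffers the mean p-EGFR per endosome toward a
# constant "quantum" across EGF doses. Receptor mass is conserved up to the
# sorting flux to late endosomes (k_le * S_e).

#' Parameter set of the p-EGFR trafficking model
#'
#' All rates are first order unless noted. Receptor amounts are in arbitrary
#' intensity units (a.u.); time in minutes; EGF dose in ng/ml.
#'
#' @param k_in EGF binding rate, per (ng/ml x min).
#' @param k_out EGF release (and concomitant dephosphorylation) rate, per min.
#' @param delta_tau Delay constant of the stimulation onset (min); the
#'   binding flux is multiplied by `1 - exp(-(t/delta_tau)^2)`.
#' @param kv0,kv1 Basal and EGF-stimulated vesicle-formation rates (per min).
#' @param Qv Half-max plasma-membrane p-EGFR of the vesicle-formation Hill
#'   term (a.u.); `q` its Hill coefficient.
#' @param w Weight of p-EGFR relative to EGFR in internalization flux
#'   partitioning (dimensionless).
#' @param s_v Mean p-EGFR per endocytic vesicle (a.u. per vesicle).
#' @param beta1,beta2 Minimum and maximum dephosphorylation rates (per min);
#'   `beta2 >= beta1`.
#' @param r Hill coefficient of the dephosphorylation sigmoid.
#' @param Q Characteristic p-EGFR amount per endosome at which
#'   dephosphorylation is half-maximal (a.u. per endosome).
#' @param k_re Early-to-recycling sorting rate (per min).
#' @param k_le Early-to-late sorting rate (per min); the only mass sink.
#' @param k_re_out Recycling-endosome-to-plasma-membrane rate (per min).
#' @param rho Homotypic early-endosome fusion rate (per min per endosome).
#' @param f Homotypic fission rate (per min).
#' @param S_total Initial plasma-membrane EGFR, `S_m(0)` (a.u.).
#' @param N_pe0 Initial endosome-number floor, avoids 0/0 in `S_pe / N_pe`.
#' @return A list of class `model_params`.
#' @export
model_params <- function(k_in = 0.007, k_out = 0.07, delta_tau = 4,
                         kv0 = 0.005, kv1 = 0.3, Qv = 14, q = 2,
                         w = 2.5, s_v = 2,
                         beta1 = 0.005, beta2 = 0.35, r = 4, Q = 8.5,
                         k_re = 0.03, k_le = 0.01, k_re_out = 0.05,
                         rho = 0.028, f = 0.003,
                         S_total = 1000, N_pe0 = 1e-6) {
  p <- list(k_in = k_in, k_out = k_out, delta_tau = delta_tau,
            kv0 = kv0, kv1 = kv1, Qv = Qv, q = q, w = w, s_v = s_v,
            beta1 = beta1, beta2 = beta2, r = r, Q = Q,
            k_re = k_re, k_le = k_le, k_re_out = k_re_out,
            rho = rho, f = f, S_total = S_total, N_pe0 = N_pe0)
  if (any(unlist(p) < 0)) stop("all model parameters must be non-negative")
  if (beta2 < beta1) stop("beta2 must be >= beta1")
  if (q < 1 || r < 1) stop("Hill coefficients q and r must be >= 1")
  if (s_v <= 0) stop("s_v must be > 0")
  structure(p, class = "model_params")
}

#' Reference parameter set
#'
#' The parameter set used throughout the package's examples and studies. It
#' is chosen to reproduce the qualitative behaviours of the sigmoidal
#' dephosphorylation model — a near-constant steady mean p-EGFR per endosome
#' across a 20-fold EGF dose range, and suppression of endosomal p-EGFR with
#' increasing homotypic fusion rate — and is not a published fit.
#'
#' @return A [model_params()] object.
#' @export
reference_params <- function() model_params()

#' EGF stimulus
#'
#' Constant (continuous stimulation) or step-down to zero at a wash time
#' (pulse-chase).
#'
#' @param c_egf EGF concentration, ng/ml, `>= 0`.
#' @param wash_time Optional time (min) at which the dose steps to 0.
#' @return A function of time returning the EGF concentration.
#' @export
stimulus <- function(c_egf, wash_time = NULL) {
  if (c_egf < 0) stop("c_egf must be >= 0")
  force(c_egf); force(wash_time)
  structure(function(t) {
    if (is.null(wash_time)) rep_len(c_egf, length(t))
    else ifelse(t < wash_time, c_egf, 0)
  }, class = "stimulus", c_egf = c_egf)
}

#' EGF-stimulated vesicle-formation rate
#'
#' `K_v = kv0 + kv1 * S_mp^q / (Qv^q + S_mp^q)`: a basal rate plus a Hill
#' term in plasma-membrane p-EGFR.
#'
#' @param S_mp Plasma-membrane p-EGFR (a.u.).
#' @param params A [model_params()].
#' @return Rate per minute.
#' @export
vesicle_formation_rate <- function(S_mp, params) {
  params$kv0 + params$kv1 * S_mp^params$q / (params$Qv^params$q + S_mp^params$q)
}

#' Sigmoidal dephosphorylation rate
#'
#' `beta1 + (beta2 - beta1) * S_pe^r / ((Q * N_pe)^r + S_pe^r)`: when the
#' p-EGFR load per endosome exceeds Q the rate switches from `beta1` toward
#' `beta2`. At `N_pe = 0` with `S_pe > 0` the limit is `beta2` (all load is
#' above threshold); at `S_pe = 0` the rate is `beta1`.
#'
#' @param S_pe Endosomal p-EGFR (a.u.).
#' @param N_pe Number of p-EGFR-positive endosomes.
#' @param params A [model_params()].
#' @return Rate per minute.
#' @export
dephosphorylation_rate <- function(S_pe, N_pe, params) {
  if (S_pe <= 0) return(params$beta1)
  hill <- S_pe^params$r / ((params$Q * N_pe)^params$r + S_pe^params$r)
  params$beta1 + (params$beta2 - params$beta1) * hill
}

#' Time derivatives of the trafficking model
#'
#' Implements the full system: EGF binding with a squared-exponential onset
#' delay, partitioning of the internalization flux between ligand-free EGFR
#' and p-EGFR with weight `w`, sigmoidal dephosphorylation in early
#' endosomes, recycling and late-endosome sorting, and endosome-number
#' dynamics `dN_pe/dt = (K_v/s_v) * (w S_mp/(S_m + w S_mp)) * S_mp
#' - rho * N_pe^2 + f * N_pe` (vesicle delivery, homotypic fusion, fission).
#'
#' @param state Named numeric vector `(S_m, S_mp, S_e, S_pe, S_re, N_pe)`,
#'   non-negative.
#' @param t Time (min).
#' @param params A [model_params()].
#' @param stim A [stimulus()].
#' @return Named numeric vector of derivatives.
#' @export
model_derivatives <- function(state, t, params, stim) {
  if (any(!is.finite(state)) || any(state < -1e-8))
    stop("state must be finite and non-negative")
  state <- pmax(state, 0)
  S_m <- state[["S_m"]]; S_mp <- state[["S_mp"]]
  S_e <- state[["S_e"]]; S_pe <- state[["S_pe"]]
  S_re <- state[["S_re"]]; N_pe <- state[["N_pe"]]
  p <- params
  delay <- if (p$delta_tau > 0) 1 - exp(-(t / p$delta_tau)^2) else 1
  bind <- p$k_in * S_m * stim(t) * delay
  Kv <- vesicle_formation_rate(S_mp, p)
  denom <- S_m + p$w * S_mp
  frac_m <- if (denom > 0) S_m / denom else 0
  frac_p <- if (denom > 0) p$w * S_mp / denom else 0
  int_m <- Kv * frac_m * S_m      # internalization of ligand-free EGFR
  int_p <- Kv * frac_p * S_mp     # internalization of p-EGFR
  deph <- dephosphorylation_rate(S_pe, N_pe, p) * S_pe
  c(
    S_m = -bind + p$k_out * S_mp - int_m + p$k_re_out * S_re,
    S_mp = bind - p$k_out * S_mp - int_p,
    S_e = int_m + deph - p$k_re * S_e - p$k_le * S_e,
    S_pe = int_p - deph,
    S_re = p$k_re * S_e - p$k_re_out * S_re,
    N_pe = int_p / p$s_v - p$rho * N_pe^2 + p$f * N_pe
  )
}

#' Simulate the trafficking model
#'
#' Integrates the six-state system with a stiff implicit solver (lsoda,
#' rtol 1e-8 / atol 1e-10) and returns both the state trajectories and the
#' four observables the model is fitted to: the number of p-EGFR endosomes
#' (`n_pe`), total endosomal p-EGFR (`s_pe`), mean p-EGFR per endosome
#' (`s_pe_per_endosome = S_pe / N_pe`, p-EGFR taken as evenly distributed),
#' and total vesicular EGFR in early endosomes (`s_vesicular = S_e + S_pe`;
#' set `include_recycling = TRUE` to add `S_re`).
#'
#' @param params A [model_params()].
#' @param stim A [stimulus()].
#' @param times Time grid (min), starting at 0.
#' @param initial_state Optional named state vector; default
#'   `S_m = S_total`, other receptor pools 0, `N_pe = N_pe0`.
#' @param include_recycling Include `S_re` in the vesicular observable.
#' @param rtol,atol Solver tolerances.
#' @return List with data.frames `trajectories` (time + 6 states) and
#'   `observables` (time + 4 observables).
#' @export
simulate_model <- function(params, stim, times, initial_state = NULL,
                           include_recycling = FALSE,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "model_params"))
  if (times[1] != 0) stop("time grid must start at 0")
  y0 <- if (is.null(initial_state))
    c(S_m = params$S_total, S_mp = 0, S_e = 0, S_pe = 0, S_re = 0,
      N_pe = params$N_pe0)
  else initial_state
  rhs <- function(t, y, parms) list(model_derivatives(y, t, params, stim))
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed; parameters: ",
         paste(names(params), signif(unlist(params), 4),
               sep = "=", collapse = " "))
  traj <- as.data.frame(sol)
  # clip solver-level negative round-off
  traj[-1][traj[-1] < 0] <- 0
  obs <- data.frame(
    time = traj$time,
    n_pe = traj$N_pe,
    s_pe = traj$S_pe,
    s_pe_per_endosome = ifelse(traj$N_pe > 0, traj$S_pe / traj$N_pe, 0),
    s_vesicular = traj$S_e + traj$S_pe +
      if (include_recycling) traj$S_re else 0
  )
  list(trajectories = traj, observables = obs)
}

#' Simulate the first-order dephosphorylation variant
#'
#' Identical system with a constant dephosphorylation rate
#' (`beta1 = beta2 = rate`); used for model discrimination against the
#' sigmoidal model.
#'
#' @param params A [model_params()]; its `beta2` is used as the constant
#'   rate unless `rate` is given.
#' @param stim,times,... Passed to [simulate_model()].
#' @param rate Optional constant dephosphorylation rate (per min).
#' @return As [simulate_model()].
#' @export
simulate_first_order <- function(params, stim, times, rate = NULL, ...) {
  r0 <- if (is.null(rate)) params$beta2 else rate
  p <- params
  p$beta1 <- r0
  p$beta2 <- r0
  class(p) <- "model_params"
  simulate_model(p, stim, times, ...)
}

#' Dose-response surface of endosomal p-EGFR over fusion rates
#'
#' Simulates the model for every combination of homotypic fusion rate `rho`
#' and EGF dose, and reports total endosomal p-EGFR (`S_pe`) at the stated
#' horizon, plus the full `N_pe` trajectories for trajectory-level
#' comparisons.
#'
#' @param params Baseline [model_params()].
#' @param rho_values Fusion rates to sweep (per min per endosome).
#' @param c_egf_values EGF doses (ng/ml).
#' @param horizon Evaluation time (min).
#' @param dt Output grid step (min).
#' @return List with `s_pe` (matrix, rows = rho, cols = dose) and
#'   `n_pe_trajectories` (long data.frame: rho, dose, time, n_pe).
#' @export
fusion_rate_sweep <- function(params, rho_values, c_egf_values,
                              horizon = 60, dt = 1) {
  times <- seq(0, horizon, by = dt)
  s_pe <- matrix(NA_real_, length(rho_values), length(c_egf_values),
                 dimnames = list(signif(rho_values, 6), signif(c_egf_values, 6)))
  tr <- list()
  for (i in seq_along(rho_values)) {
    p <- params
    p$rho <- rho_values[i]
    class(p) <- "model_params"
    for (j in seq_along(c_egf_values)) {
      sim <- simulate_model(p, stimulus(c_egf_values[j]), times)
      s_pe[i, j] <- sim$observables$s_pe[length(times)]
      tr[[length(tr) + 1]] <- data.frame(
        rho = rho_values[i], dose = c_egf_values[j],
        time = times, n_pe = sim$observables$n_pe)
    }
  }
  list(s_pe = s_pe, n_pe_trajectories = do.call(rbind, tr))
}
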