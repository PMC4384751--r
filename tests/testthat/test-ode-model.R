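test_that("vesicle formation rate has basal, half-max and saturation limits", {
  p <- params_with_overrides(kv0 = 0.1, kv1 = 0.9, Qv = 50, q = 2)
  expect_equal(vesicle_formation_rate(0, p), 0.1)
  expect_equal(vesicle_formation_rate(50, p), 0.55)
  expect_equal(vesicle_formation_rate(1e9, p), 1.0, tolerance = 1e-6)
})

test_that("dephosphorylation rate spans beta1..beta2 with midpoint at Q", {
  p <- params_with_overrides(beta1 = 0.01, beta2 = 0.20, Q = 100, r = 2)
  expect_equal(dephosphorylation_rate(0, 10, p), 0.01)
  expect_equal(dephosphorylation_rate(1000, 10, p), 0.105)  # load/endosome = Q
  expect_equal(dephosphorylation_rate(1e9, 10, p), 0.20, tolerance = 1e-6)
  # N_pe = 0 with load present: everything is above threshold
  expect_equal(dephosphorylation_rate(5, 0, p), 0.20)
  # large Hill coefficient approaches a step at Q per endosome
  ps <- params_with_overrides(beta1 = 0.01, beta2 = 0.20, Q = 100, r = 60)
  expect_equal(dephosphorylation_rate(800, 10, ps), 0.01, tolerance = 1e-3)
  expect_equal(dephosphorylation_rate(1250, 10, ps), 0.20, tolerance = 1e-3)
})

test_that("derivatives vanish on the empty state and delay kills t=0 binding", {
  p <- reference_params()
  zero <- c(S_m = 0, S_mp = 0, S_e = 0, S_pe = 0, S_re = 0, N_pe = 0)
  expect_equal(model_derivatives(zero, 5, p, stimulus(10)), zero)
  full <- c(S_m = 1000, S_mp = 0, S_e = 0, S_pe = 0, S_re = 0, N_pe = 0)
  d0 <- model_derivatives(full, 0, p, stimulus(10))
  expect_equal(d0[["S_mp"]], 0)  # squared-exponential onset delay
  expect_error(model_derivatives(full * NA, 0, p, stimulus(10)), "finite")
})

test_that("receptor mass balance holds symbolically in the derivatives", {
  set.seed(6)
  p0 <- params_with_overrides(k_le = 0)
  pools <- c("S_m", "S_mp", "S_e", "S_pe", "S_re")
  for (i in 1:20) {
    st <- c(S_m = runif(1, 0, 1000), S_mp = runif(1, 0, 500),
            S_e = runif(1, 0, 500), S_pe = runif(1, 0, 500),
            S_re = runif(1, 0, 300), N_pe = runif(1, 0, 50))
    d <- model_derivatives(st, runif(1, 0, 60), p0, stimulus(10))
    expect_lt(abs(sum(d[pools])), 1e-12 * sum(abs(d[pools])) + 1e-12)
  }
  p1 <- params_with_overrides(k_le = 0.02)
  st <- c(S_m = 500, S_mp = 100, S_e = 100, S_pe = 50, S_re = 25, N_pe = 10)
  d <- model_derivatives(st, 30, p1, stimulus(10))
  expect_equal(sum(d[pools]), -2.0, tolerance = 1e-12)
})

test_that("without stimulus or basal internalization the state is steady", {
  p <- params_with_overrides(kv0 = 0)
  sim <- simulate_model(p, stimulus(0), seq(0, 60, 5),
                        initial_state = c(S_m = 1, S_mp = 0, S_e = 0,
                                          S_pe = 0, S_re = 0, N_pe = 0))
  expect_equal(sim$trajectories$S_m, rep(1, 13), tolerance = 1e-9)
  expect_true(all(sim$trajectories[, -1] >= 0))
})

test_that("endosome number follows the logistic fusion-fission dynamics", {
  p <- params_with_overrides(f = 0.05, rho = 0.001)
  times <- seq(0, 10 / 0.05, by = 1)
  sim <- simulate_model(p, stimulus(0), times,
                        initial_state = c(S_m = 0, S_mp = 0, S_e = 0,
                                          S_pe = 0, S_re = 0, N_pe = 10))
  n <- sim$observables$n_pe
  # matches the closed-form logistic solution along the whole trajectory
  expect_equal(n, logistic_npe(times, 10, 0.05, 0.001), tolerance = 1e-6)
  # converges to the f/rho fixed point
  expect_lt(abs(n[length(n)] - 50) / 50, 0.001)
})

test_that("receptor loss equals the integrated late-endosome flux", {
  p <- reference_params()
  times <- seq(0, 60, by = 1)
  # augment the system with a cumulative-loss state fed by k_le * S_e
  rhs <- function(t, y, parms) {
    d <- model_derivatives(y[1:6], t, p, stimulus(10))
    list(c(d, L = p$k_le * y[["S_e"]]))
  }
  y0 <- c(S_m = p$S_total, S_mp = 0, S_e = 0, S_pe = 0, S_re = 0,
          N_pe = p$N_pe0, L = 0)
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
  tot <- rowSums(sol[, c("S_m", "S_mp", "S_e", "S_pe", "S_re")])
  lost <- tot[1] - tot[length(times)]
  expect_gt(lost, 0)
  expect_equal(lost, unname(sol[length(times), "L"]), tolerance = 1e-6)
})

test_that("solutions are stable under grid refinement and tighter tolerances", {
  p <- reference_params()
  s1 <- simulate_model(p, stimulus(10), seq(0, 60, 5))
  s2 <- simulate_model(p, stimulus(10), seq(0, 60, 0.5),
                       rtol = 1e-9, atol = 1e-11)
  sub <- s2$observables[s2$observables$time %in% seq(0, 60, 5), ]
  for (nm in c("n_pe", "s_pe", "s_vesicular"))
    expect_equal(s1$observables[[nm]], sub[[nm]],
                 tolerance = 1e-5)
})

test_that("first-order variant reduces to the full model when beta1 = beta2", {
  p <- params_with_overrides(beta1 = 0.35, beta2 = 0.35)
  s_full <- simulate_model(p, stimulus(5), seq(0, 40, 5))
  s_fo <- simulate_first_order(p, stimulus(5), seq(0, 40, 5))
  expect_equal(s_full$observables, s_fo$observables, tolerance = 1e-10)
})

test_that("pulse-chase stimulus shuts off binding at the wash time", {
  p <- reference_params()
  stim <- stimulus(10, wash_time = 10)
  expect_equal(stim(c(5, 9.9, 10, 30)), c(10, 10, 0, 0))
  s_pulse <- simulate_model(p, stim, seq(0, 60, 5))
  s_cont <- simulate_model(p, stimulus(10), seq(0, 60, 5))
  expect_lt(tail(s_pulse$observables$s_pe, 1), tail(s_cont$observables$s_pe, 1))
})

test_that("fusion sweep at the baseline rate reproduces a direct simulation", {
  p <- reference_params()
  sw <- fusion_rate_sweep(p, p$rho, c(1, 10), horizon = 30)
  direct <- simulate_model(p, stimulus(10), seq(0, 30, 1))
  expect_equal(sw$s_pe[1, "10"], tail(direct$observables$s_pe, 1),
               tolerance = 1e-10)
})
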