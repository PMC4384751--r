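test_that("generators are deterministic under a fixed seed", {
  cfg <- synth_config(seed = 42L)
  t1 <- generate_endosome_table(cfg)
  t2 <- generate_endosome_table(cfg)
  expect_identical(t1, t2)
  expect_identical(generate_fret_channels(t1, cfg),
                   generate_fret_channels(t2, cfg))
  expect_identical(generate_bleach_series(cfg), generate_bleach_series(cfg))
  a1 <- generate_area_populations(c(-2.2, 0.7), c(-2.7, 0.7), n = 500, seed = 3)
  a2 <- generate_area_populations(c(-2.2, 0.7), c(-2.7, 0.7), n = 500, seed = 3)
  expect_identical(a1$base, a2$base)
  p <- reference_params()
  tc1 <- generate_timecourse_data(p, doses = c(1, 10), times = c(0, 10, 30),
                                  ode_noise_cv = 0.05, seed = 5)
  tc2 <- generate_timecourse_data(p, doses = c(1, 10), times = c(0, 10, 30),
                                  ode_noise_cv = 0.05, seed = 5)
  expect_identical(tc1, tc2)
})

test_that("per-image endosome counts follow the Poisson law", {
  cfg <- synth_config(seed = 7L, n_images = 10L, cell_area_per_image = 1000,
                      endosome_density = 20)
  tab <- generate_endosome_table(cfg)
  expect_lt(abs(nrow(tab) - 200), 3 * sqrt(200))
  expect_setequal(unique(tab$image_id), 1:10)
  expect_true(all(tab$area_um2 > 0) && all(tab$I_gfp > 0))
  expect_true(all(tab$x >= 0 & tab$x <= sqrt(1000)))
})

test_that("degenerate log-normal (log-sd 0) gives exactly unit intensities", {
  cfg <- synth_config(seed = 1L,
                      intensity_lognormal = list(gfp = c(0, 0), ptyr = c(0, 0)))
  tab <- generate_endosome_table(cfg)
  expect_equal(tab$I_gfp, rep(1, nrow(tab)))
  expect_equal(tab$I_ptyr, rep(1, nrow(tab)))
})

test_that("configuration validation rejects out-of-range values", {
  expect_error(synth_config(endosome_density = -1), "endosome_density")
  expect_error(synth_config(fret_true_fraction = 1.5), "fret_true_fraction")
  expect_error(synth_config(bleach = list(unit_intensity = 200,
                                          bleach_prob_per_frame = 1.2,
                                          noise_sd = 0, n_frames = 10,
                                          n_objects = 5,
                                          molecules_per_object_law =
                                            list(law = "fixed", n = 1))),
               "bleach_prob")
})

test_that("FRET channel ratios follow the configured bleed-through mixture", {
  mix <- ratio_mixture(c(0.6, 0.4), c(0.35, 0.9), c(0.1, 0.25))
  cfg <- synth_config(seed = 11L, n_images = 50L, cell_area_per_image = 2000,
                      endosome_density = 100, fret_true_fraction = 0,
                      bleedthrough_mixture = mix)
  tab <- generate_fret_channels(generate_endosome_table(cfg), cfg)
  expect_gt(nrow(tab), 5000)
  ratios <- tab$I_fret / tab$I_ptyr
  cdf <- function(q) 0.6 * pnorm(q, 0.35, 0.1) + 0.4 * pnorm(q, 0.9, 0.25)
  ks <- suppressWarnings(stats::ks.test(ratios, cdf))
  expect_gt(ks$p.value, 0.01)
  # F_true stored and zero in this no-signal configuration
  expect_equal(tab$F_true, rep(0, nrow(tab)))
})

test_that("single near-degenerate mixture component gives I = F_true + mu*T", {
  mix <- ratio_mixture(1, 1.3, 1e-9)
  cfg <- synth_config(seed = 2L, fret_true_fraction = 0.25,
                      bleedthrough_mixture = mix)
  tab <- generate_fret_channels(generate_endosome_table(cfg), cfg)
  expect_equal(tab$I_fret, tab$F_true + 1.3 * tab$I_ptyr, tolerance = 1e-6)
  expect_error(generate_fret_channels(tab[0, ], cfg), "non-empty")
})

test_that("bleaching series honour degenerate limits", {
  one <- function(p) synth_config(seed = 1L, bleach = list(
    unit_intensity = 100, bleach_prob_per_frame = p, noise_sd = 0,
    n_frames = 5L, n_objects = 3L,
    molecules_per_object_law = list(law = "fixed", n = 1)))
  tr <- generate_bleach_series(one(1))
  for (id in 1:3)
    expect_equal(tr$intensity[tr$object_id == id], c(100, 0, 0, 0, 0))
  tr0 <- generate_bleach_series(one(0))
  expect_true(all(tr0$intensity == 100))
})

test_that("mean bleaching intensity decays geometrically", {
  cfg <- synth_config(seed = 9L, bleach = list(
    unit_intensity = 200, bleach_prob_per_frame = 0.1, noise_sd = 0,
    n_frames = 15L, n_objects = 500L,
    molecules_per_object_law = list(law = "poisson", mean = 30)))
  tr <- generate_bleach_series(cfg)
  for (k in c(1, 5, 10, 15)) {
    x <- tr$intensity[tr$frame == k]
    expected <- 200 * 30 * 0.9^(k - 1)
    expect_lt(abs(mean(x) - expected), 3 * sd(x) / sqrt(500))
  }
})

test_that("noise-free time courses equal the simulator output", {
  p <- reference_params()
  times <- seq(0, 30, by = 10)
  tc <- generate_timecourse_data(p, doses = c(1, 10), times = times,
                                 ode_noise_cv = 0, seed = 1)
  expect_equal(tc$value, tc$value_true)
  sim <- simulate_model(p, stimulus(10), times)
  got <- tc$value[tc$dose == 10 & tc$observable == "s_pe"]
  expect_equal(got, sim$observables$s_pe, tolerance = 1e-12)
  # shape: |doses| x |times| rows per observable
  expect_equal(nrow(tc), 2 * length(times) * 4)
  expect_true(all(tc$sem > 0))
})

test_that("time-course noise magnitude matches the configured CV", {
  p <- reference_params()
  times <- c(0, 20, 40, 60)
  reps <- sapply(1:20, function(i)
    generate_timecourse_data(p, doses = 10, times = times,
                             ode_noise_cv = 0.05, seed = 1000 + i)$value)
  truth <- generate_timecourse_data(p, doses = 10, times = times,
                                    ode_noise_cv = 0, seed = 1)$value_true
  sel <- truth > 0.1 * max(truth)
  rel_sd <- apply(reps[sel, , drop = FALSE], 1, sd) / truth[sel]
  expect_lt(abs(median(rel_sd) - 0.05), 0.3 * 0.05)
})

test_that("identical area populations give a near-zero difference curve", {
  pops <- generate_area_populations(c(-2.2, 0.7), c(-2.2, 0.7), n = 5000,
                                    seed = 4)
  rng <- range(c(pops$base, pops$shifted)) * c(0.99, 1.01)
  hb <- log_binned_histogram(pops$base, 40, rng)
  hs <- log_binned_histogram(pops$shifted, 40, rng)
  d <- histogram_difference(hs, hb)
  expect_lt(max(abs(d$diff)), 0.05)
  expect_error(generate_area_populations(c(0, 1), c(0, 1), n = 50), "n must")
})
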