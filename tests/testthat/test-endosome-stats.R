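test_that("intensity and density summaries follow their definitions", {
  expect_equal(total_integral_intensity(c(10, 20, 30), 1000), 60)
  expect_equal(total_integral_intensity(numeric(0), 1000), 0)
  expect_equal(total_integral_intensity(c(10, 20, 30), 2000), 30)
  expect_error(total_integral_intensity(1, 0), "cell_area")

  expect_equal(mean_integral_per_endosome(c(10, 20, 30)), 20)
  expect_equal(mean_integral_per_endosome(7), 7)
  set.seed(1)
  v <- runif(50)
  expect_equal(mean_integral_per_endosome(v),
               mean_integral_per_endosome(sample(v)))
  expect_error(mean_integral_per_endosome(numeric(0)), "undefined")

  expect_equal(endosome_number_density(3, 1000), 3)
  expect_equal(endosome_number_density(0, 1000), 0)
  expect_equal(endosome_number_density(50, 2500), 20)
})

test_that("log-binned histograms have geometric edges and conserve counts", {
  set.seed(2)
  v <- exp(runif(500, log(0.01), log(10)))
  h <- log_binned_histogram(v, 40)
  ratios <- h$edges[-1] / h$edges[-41]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-10)
  expect_equal(sum(h$counts), 500)
  h1 <- log_binned_histogram(rep(2, 10), 5, range = c(1, 4))
  expect_equal(sum(h1$counts > 0), 1)
  expect_error(log_binned_histogram(c(1, -2, 3)), "offending rows")
})

test_that("histogram normalization sums to one and is idempotent", {
  h <- log_binned_histogram(c(1, 2, 4, 8), 4, range = c(0.9, 9))
  n1 <- normalize_histogram(h)
  expect_equal(sum(n1$counts), 1, tolerance = 1e-12)
  expect_equal(normalize_histogram(n1)$counts, n1$counts)
  h0 <- h
  h0$counts <- rep(0L, 4)
  expect_error(normalize_histogram(h0), "empty")
})

test_that("histogram differences are antisymmetric and mass-free", {
  set.seed(3)
  a <- rlnorm(2000, 0, 0.5)
  b <- rlnorm(2000, 0.4, 0.5)
  rng <- range(c(a, b)) * c(0.99, 1.01)
  ha <- log_binned_histogram(a, 30, rng)
  hb <- log_binned_histogram(b, 30, rng)
  d1 <- histogram_difference(ha, hb)
  d2 <- histogram_difference(hb, ha)
  expect_equal(sum(d1$diff), 0, tolerance = 1e-12)
  expect_equal(d1$diff, -d2$diff)
  expect_equal(histogram_difference(ha, ha)$diff, rep(0, 30))
  hm <- log_binned_histogram(a, 30, rng * c(0.9, 1.1))
  expect_error(histogram_difference(ha, hm), "edges")
  # enrichment over the full range is zero; complementary halves cancel
  expect_equal(enrichment_integral(d1, rng), 0, tolerance = 1e-12)
  cut <- d1$edges[16]
  expect_equal(enrichment_integral(d1, c(rng[1], cut)) +
                 enrichment_integral(d1, c(cut, rng[2])), 0,
               tolerance = 1e-12)
})

test_that("log-normal histogram fit recovers exact and sampled parameters", {
  h <- log_binned_histogram(exp(seq(log(0.05), log(5), length.out = 200)), 30)
  h$counts <- 0.8 * dlnorm(h$centers, -0.7, 0.45) * diff(h$edges)
  h$normalized <- FALSE
  fit <- fit_lognormal(h)
  expect_equal(fit$meanlog, -0.7, tolerance = 1e-6)
  expect_equal(fit$sdlog, 0.45, tolerance = 1e-6)

  set.seed(8)
  s <- rlnorm(10000, -2.2, 0.7)
  fs <- fit_lognormal(s)
  expect_equal(fs$meanlog, -2.2, tolerance = 0.05 * 2.2)
  expect_equal(fs$sdlog, 0.7, tolerance = 0.05 * 0.7 / 0.7)
  expect_lt(fs$relative_residual, 0.1)

  # clearly bimodal input leaves a much larger residual than a true sample
  bim <- c(rlnorm(5000, -1, 0.25), rlnorm(5000, 1, 0.25))
  fb <- fit_lognormal(bim)
  expect_gt(fb$relative_residual, 0.1)
  expect_gt(fb$relative_residual, 2 * fs$relative_residual)
  expect_error(fit_lognormal(rep(1, 10), n_bins = 40), "nonzero bins")
})

test_that("two-lobe signed log-normal fit recovers both components", {
  x <- exp(seq(log(0.02), log(8), length.out = 120))
  y <- -0.5 * dlnorm(x, log(0.2), 0.3) + 0.8 * dlnorm(x, log(1.5), 0.45)
  fit <- fit_two_lognormal(x, y)
  comp <- fit$components
  expect_equal(comp$amplitude, c(-0.5, 0.8), tolerance = 1e-3)
  expect_equal(comp$meanlog, c(log(0.2), log(1.5)), tolerance = 1e-3)
  expect_equal(comp$sdlog, c(0.3, 0.45), tolerance = 1e-3)
  # signs of the lobes preserved
  expect_lt(comp$amplitude[1], 0)
  expect_gt(comp$amplitude[2], 0)
})

test_that("disc-overlap colocalization handles identity, separation, boundary", {
  set.seed(5)
  a <- data.frame(image_id = 1, x = runif(20, 0, 30), y = runif(20, 0, 30),
                  area_um2 = runif(20, 0.05, 0.3), I = runif(20, 10, 100))
  expect_equal(colocalization_fraction(a, a)$fraction, 1.0)
  b <- a
  b$x <- b$x + 100
  expect_equal(colocalization_fraction(a, b)$fraction, 0.0)
  expect_error(colocalization_fraction(a, a, overlap_threshold = 1.2),
               "threshold")

  # boundary: lens area exactly 30% of the smaller disc is excluded (strict >)
  r <- sqrt(1 / pi)
  dstar <- uniroot(function(d) disc_lens_area(r, r, d) - 0.3,
                   c(1e-6, 2 * r), tol = 1e-12)$root
  mk <- function(d) list(
    data.frame(image_id = 1, x = 0, y = 0, area_um2 = 1),
    data.frame(image_id = 1, x = d, y = 0, area_um2 = 1))
  just_in <- mk(dstar - 1e-6)
  just_out <- mk(dstar + 1e-6)
  expect_equal(colocalization_fraction(just_in[[1]], just_in[[2]])$fraction, 1)
  expect_equal(colocalization_fraction(just_out[[1]], just_out[[2]])$fraction, 0)

  # intensity-weighted variant
  cw <- colocalization_fraction(a, a, intensity_col = "I")
  expect_equal(cw$fraction_intensity, 1)
})

test_that("bi-exponential fit is exact on noise-free curves", {
  t <- seq(0, 60, length.out = 9)
  f1 <- fit_timecourse(t, 5 * exp(-t / 30))
  expect_equal(f1$tau_decay, 30, tolerance = 1e-4)
  expect_true(f1$reliable)

  y <- -5 * exp(-t / 5) + 5 * exp(-t / 30)
  f2 <- fit_timecourse(t, y)
  expect_equal(f2$A, -5, tolerance = 1e-4)
  expect_equal(f2$tau1, 5, tolerance = 1e-4)
  expect_equal(f2$B, 5, tolerance = 1e-4)
  expect_equal(f2$tau_decay, 30, tolerance = 1e-4)
})

test_that("monotone rising data give an unreliable decline constant", {
  t <- seq(0, 60, length.out = 9)
  f <- fit_timecourse(t, 10 * (1 - exp(-t / 20)))
  expect_false(f$reliable)
})

test_that("weighted fitting honours SEM weights", {
  t <- seq(0, 60, length.out = 9)
  y <- -4 * exp(-t / 6) + 6 * exp(-t / 25)
  f <- fit_timecourse(t, y, sems = rep(0.05, 9))
  expect_equal(f$tau_decay, 25, tolerance = 1e-3)
  expect_error(fit_timecourse(t, y, sems = rep(0, 9)), "sems")
  expect_error(fit_timecourse(t[1:4], y[1:4]), "at least 5")
})
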