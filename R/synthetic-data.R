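# Synthetic microscopy-scale data with the statistical structure the
# downstream analyses assume: log-normal per-endosome intensities and areas,
# Poisson object counts per image, Gaussian-mixture spectral bleed-through,
# discrete single-molecule bleaching steps, and noisy trajectories of the
# trafficking ODE model. Ground-truth columns (F_true, n_true, value_true)
# are always written alongside; analysis code must never read them — they
# exist as an oracle surface for tests.
#
# Reproducibility scheme: one global seed; each generator seeds the RNG with
# seed + a fixed per-generator offset (endosome table +1, FRET channels +2,
# bleach series +3, time courses +4, area populations +5), so generators are
# individually reproducible and mutually independent.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe a typical quantitative-endocytosis imaging experiment:
#' HeLa-scale cells imaged at ~20 endosomes per 1000 um^2, broad (log-normal)
#' per-endosome integral intensities, sub-um^2 log-normal cross-sections,
#' a two-component Gaussian bleed-through ratio, and GFP photobleaching at a
#' per-frame bleaching probability of 0.08 over 40 frames.
#'
#' @param seed Integer seed fixing all outputs bit-for-bit.
#' @param n_images Number of imaged fields.
#' @param cell_area_per_image Cell-covered area per image (um^2).
#' @param endosome_density Mean endosomes per 1000 um^2.
#' @param intensity_lognormal Named list of `c(meanlog, sdlog)` per channel;
#'   channels `gfp` and `ptyr` are required.
#' @param area_lognormal `c(meanlog, sdlog)` of cross-sectional area (um^2).
#' @param fret_true_fraction Fraction of the GFP intensity re-emitted as true
#'   FRET signal, in `[0, 1]`.
#' @param bleedthrough_mixture A [ratio_mixture()] for the bleed-through
#'   ratio m = (I - F)/T.
#' @param bleach List with `unit_intensity` (a.u. per fluorophore),
#'   `bleach_prob_per_frame` in `[0, 1]`, `noise_sd` (a.u.), `n_frames >= 2`,
#'   `n_objects`, and `molecules_per_object_law` — either
#'   `list(law = "poisson", mean = m)` or `list(law = "fixed", n = k)`.
#' @param ode_noise_cv Relative SD of multiplicative noise applied to model
#'   observables in [generate_timecourse_data()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_images = 10L,
                         cell_area_per_image = 1000,
                         endosome_density = 20,
                         intensity_lognormal = list(gfp = c(6.5, 0.9),
                                                    ptyr = c(5.0, 0.9)),
                         area_lognormal = c(-2.2, 0.7),
                         fret_true_fraction = 0.5,
                         bleedthrough_mixture = ratio_mixture(
                           c(0.6, 0.4), c(0.35, 0.9), c(0.1, 0.25)),
                         bleach = list(unit_intensity = 200,
                                       bleach_prob_per_frame = 0.08,
                                       noise_sd = 50,
                                       n_frames = 40L,
                                       n_objects = 500L,
                                       molecules_per_object_law =
                                         list(law = "poisson", mean = 30)),
                         ode_noise_cv = 0.05) {
  if (endosome_density <= 0) stop("endosome_density must be > 0")
  if (cell_area_per_image <= 0) stop("cell_area_per_image must be > 0")
  if (fret_true_fraction < 0 || fret_true_fraction > 1)
    stop("fret_true_fraction must be in [0, 1]")
  for (ch in c("gfp", "ptyr"))
    if (is.null(intensity_lognormal[[ch]]))
      stop("intensity_lognormal must define channel '", ch, "'")
  p <- bleach$bleach_prob_per_frame
  if (p < 0 || p > 1) stop("bleach_prob_per_frame must be in [0, 1]")
  if (bleach$noise_sd < 0) stop("bleach noise_sd must be >= 0")
  if (bleach$unit_intensity <= 0) stop("unit_intensity must be > 0")
  if (ode_noise_cv < 0) stop("ode_noise_cv must be >= 0")
  structure(list(seed = as.integer(seed), n_images = as.integer(n_images),
                 cell_area_per_image = cell_area_per_image,
                 endosome_density = endosome_density,
                 intensity_lognormal = intensity_lognormal,
                 area_lognormal = area_lognormal,
                 fret_true_fraction = fret_true_fraction,
                 bleedthrough_mixture = bleedthrough_mixture,
                 bleach = bleach,
                 ode_noise_cv = ode_noise_cv),
            class = "synth_config")
}

#' Generate a per-endosome object table
#'
#' One row per detected endosome. Per-image object counts are
#' Poisson(density x area / 1000); intensities and areas are log-normal;
#' positions are uniform in a square field of the configured area.
#'
#' @param config A [synth_config()].
#' @return A data.frame with columns `image_id, x, y, area_um2, I_gfp,
#'   I_ptyr` (positions in um, areas in um^2, intensities in a.u.).
#' @export
generate_endosome_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  side <- sqrt(config$cell_area_per_image)
  lam <- config$endosome_density * config$cell_area_per_image / 1000
  counts <- stats::rpois(config$n_images, lam)
  n <- sum(counts)
  il <- config$intensity_lognormal
  data.frame(
    image_id = rep(seq_len(config$n_images), counts),
    x = stats::runif(n, 0, side),
    y = stats::runif(n, 0, side),
    area_um2 = stats::rlnorm(n, config$area_lognormal[1], config$area_lognormal[2]),
    I_gfp = stats::rlnorm(n, il$gfp[1], il$gfp[2]),
    I_ptyr = stats::rlnorm(n, il$ptyr[1], il$ptyr[2])
  )
}

#' Add a FRET channel with spectral bleed-through to an object table
#'
#' Draws a bleed-through ratio m per object from the configured mixture and
#' sets `I_fret = F_true + m * I_ptyr`, where the true FRET signal is
#' `F_true = fret_true_fraction * I_gfp`. `F_true` is retained for oracle
#' comparison only.
#'
#' @param records Object table from [generate_endosome_table()]; non-empty.
#' @param config A [synth_config()].
#' @return `records` with added columns `I_fret` and `F_true`.
#' @export
generate_fret_channels <- function(records, config) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(records) == 0) stop("records must be non-empty")
  mix <- config$bleedthrough_mixture
  stopifnot(inherits(mix, "ratio_mixture"))
  set.seed(config$seed + 2L)
  n <- nrow(records)
  comp <- sample.int(length(mix$weights), n, replace = TRUE, prob = mix$weights)
  m <- stats::rnorm(n, mix$means[comp], mix$sds[comp])
  records$F_true <- config$fret_true_fraction * records$I_gfp
  records$I_fret <- records$F_true + m * records$I_ptyr
  records
}

draw_molecule_counts <- function(law, n) {
  switch(law$law,
    poisson = stats::rpois(n, law$mean),
    fixed = rep.int(as.integer(law$n), n),
    lognormal = pmax(1L, as.integer(round(stats::rlnorm(n, law$meanlog, law$sdlog)))),
    stop("unknown molecules_per_object_law: ", law$law)
  )
}

#' Generate photobleaching intensity series
#'
#' Each object starts with a number of fluorophores drawn from the
#' configured law; every surviving fluorophore bleaches independently with
#' the per-frame probability between consecutive frames. The recorded frame
#' intensity is (surviving fluorophores) x unit intensity plus additive
#' Gaussian noise. The true surviving count per frame is stored in `n_true`.
#'
#' @param config A [synth_config()]; `config$bleach$n_frames >= 2`.
#' @return A data.frame with columns `object_id, frame, intensity, n_true`
#'   (frames numbered from 1; bleaching acts between frames).
#' @export
generate_bleach_series <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  b <- config$bleach
  if (b$n_frames < 2) stop("n_frames must be >= 2")
  set.seed(config$seed + 3L)
  n_obj <- b$n_objects
  n0 <- draw_molecule_counts(b$molecules_per_object_law, n_obj)
  nf <- b$n_frames
  surv <- matrix(0L, n_obj, nf)
  surv[, 1] <- n0
  for (k in 2:nf)
    surv[, k] <- stats::rbinom(n_obj, surv[, k - 1], 1 - b$bleach_prob_per_frame)
  noise <- if (b$noise_sd > 0)
    matrix(stats::rnorm(n_obj * nf, 0, b$noise_sd), n_obj, nf)
  else matrix(0, n_obj, nf)
  data.frame(
    object_id = rep(seq_len(n_obj), each = nf),
    frame = rep(seq_len(nf), n_obj),
    intensity = as.vector(t(surv * b$unit_intensity + noise)),
    n_true = as.vector(t(surv))
  )
}

#' Generate noisy multi-dose time-course data from the trafficking model
#'
#' Simulates the ODE model at each EGF dose and emits the four fitted
#' observables (`n_pe`, `s_pe`, `s_pe_per_endosome`, `s_vesicular`) with
#' multiplicative Gaussian noise of the stated coefficient of variation.
#' The SEM column is `cv * value`, floored at 5% of the observable's
#' per-dose maximum times `cv` so that early near-zero points do not get
#' unbounded weight in fitting.
#'
#' @param params A [model_params()] set.
#' @param doses EGF concentrations (ng/ml).
#' @param times Sampling times in minutes; must include 0.
#' @param ode_noise_cv Relative SD of the multiplicative noise (0 = exact).
#' @param seed Integer seed.
#' @return A data.frame with columns `dose, observable, time, value, sem,
#'   value_true` (`value_true` is the noise-free model output, for tests).
#' @export
generate_timecourse_data <- function(params, doses = c(0.5, 1, 5, 10),
                                     times = seq(0, 60, by = 5),
                                     ode_noise_cv = 0.05, seed = 1L) {
  if (!0 %in% times) stop("times must include 0")
  set.seed(as.integer(seed) + 4L)
  out <- vector("list", length(doses))
  for (d in seq_along(doses)) {
    sim <- simulate_model(params, stimulus(doses[d]), times)
    obs <- sim$observables
    long <- do.call(rbind, lapply(
      c("n_pe", "s_pe", "s_pe_per_endosome", "s_vesicular"),
      function(nm) data.frame(dose = doses[d], observable = nm,
                              time = obs$time, value_true = obs[[nm]])))
    cv <- ode_noise_cv
    long$value <- if (cv > 0)
      long$value_true * (1 + stats::rnorm(nrow(long), 0, cv))
    else long$value_true
    sem_floor <- stats::ave(long$value_true, long$observable,
                            FUN = function(v) 0.05 * max(v))
    long$sem <- pmax(cv * long$value_true, cv * sem_floor)
    if (cv == 0) long$sem <- pmax(sem_floor, .Machine$double.eps)
    out[[d]] <- long
  }
  res <- do.call(rbind, out)
  res[, c("dose", "observable", "time", "value", "sem", "value_true")]
}

#' Generate paired endosome-area populations
#'
#' Two log-normal area samples (control and condition) for exercising the
#' histogram-difference machinery; the generating CDFs are returned so that
#' enrichment integrals can be checked against the analytic CDF difference.
#'
#' @param base_lognormal,shifted_lognormal `c(meanlog, sdlog)` of the
#'   control and condition area distributions (um^2).
#' @param n Sample size per population, `>= 100`.
#' @param seed Integer seed.
#' @return List with `base`, `shifted` (numeric samples) and `cdf_base`,
#'   `cdf_shifted` (functions of area).
#' @export
generate_area_populations <- function(base_lognormal, shifted_lognormal,
                                      n = 2000, seed = 1L) {
  if (n < 100) stop("n must be >= 100")
  set.seed(as.integer(seed) + 5L)
  list(
    base = stats::rlnorm(n, base_lognormal[1], base_lognormal[2]),
    shifted = stats::rlnorm(n, shifted_lognormal[1], shifted_lognormal[2]),
    cdf_base = function(x) stats::plnorm(x, base_lognormal[1], base_lognormal[2]),
    cdf_shifted = function(x) stats::plnorm(x, shifted_lognormal[1], shifted_lognormal[2])
  )
}
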