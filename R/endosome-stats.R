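# Per-endosome and per-image summary statistics, log-binned histogram
# machinery, log-normal distribution fits, disc-overlap colocalization, and
# bi-exponential time-course fitting.

#' Total integral intensity per 1000 um^2
#'
#' Sum of per-endosome integral intensities in an image (or image set),
#' normalized by the cell-covered area.
#'
#' @param intensities Per-endosome integral intensities (a.u.).
#' @param cell_area Cell-covered area (um^2), `> 0`.
#' @return a.u. per 1000 um^2.
#' @export
total_integral_intensity <- function(intensities, cell_area) {
  if (cell_area <= 0) stop("cell_area must be > 0")
  sum(intensities) * 1000 / cell_area
}

#' Mean integral intensity per endosome
#'
#' Arithmetic mean over endosomes (averaging by the total number of
#' endosomes). An empty set is an error, deliberately distinct from 0.
#'
#' @param intensities Per-endosome integral intensities (a.u.).
#' @return a.u.
#' @export
mean_integral_per_endosome <- function(intensities) {
  if (!length(intensities)) stop("no endosomes: mean intensity is undefined")
  mean(intensities)
}

#' Endosome number density per 1000 um^2
#'
#' @param n_endosomes Endosome count (or a table whose rows are counted).
#' @param cell_area Cell-covered area (um^2), `> 0`.
#' @return Endosomes per 1000 um^2.
#' @export
endosome_number_density <- function(n_endosomes, cell_area) {
  if (cell_area <= 0) stop("cell_area must be > 0")
  if (is.data.frame(n_endosomes)) n_endosomes <- nrow(n_endosomes)
  n_endosomes * 1000 / cell_area
}

#' Histogram with bins linear on a logarithmic scale
#'
#' Geometric (constant-ratio) bin edges spanning the observed range padded
#' by 5% on the log scale (or an explicit range). Total counts are
#' conserved.
#'
#' @param values Strictly positive values (e.g. endosome areas in um^2).
#' @param n_bins Number of bins.
#' @param range Optional `c(lo, hi)` range; values outside it are an error.
#' @return List of class `log_histogram`: `edges`, `centers` (geometric bin
#'   midpoints), `counts`, `normalized` flag.
#' @export
log_binned_histogram <- function(values, n_bins = 40, range = NULL) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("values must be positive and finite; offending rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (is.null(range)) {
    lr <- log(range(values))
    # degenerate (single-valued) samples still get bins of nonzero width
    pad <- max(0.05 * diff(lr), 1e-9)
    range <- exp(c(lr[1] - pad, lr[2] + pad))
  }
  edges <- exp(seq(log(range[1]), log(range[2]), length.out = n_bins + 1))
  if (any(values < range[1] | values > range[2]))
    stop("values outside the histogram range")
  idx <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  structure(list(edges = edges,
                 centers = sqrt(edges[-1] * edges[-(n_bins + 1)]),
                 counts = tabulate(idx, nbins = n_bins),
                 normalized = FALSE),
            class = "log_histogram")
}

#' Normalize a histogram to unit total
#'
#' Scales bin values so they sum to one. Idempotent; an all-zero histogram
#' is an error.
#'
#' @param h A [log_binned_histogram()].
#' @return The histogram with `counts` summing to 1.
#' @export
normalize_histogram <- function(h) {
  stopifnot(inherits(h, "log_histogram"))
  tot <- sum(h$counts)
  if (tot == 0) stop("cannot normalize an empty histogram")
  h$counts <- h$counts / tot
  h$normalized <- TRUE
  h
}

#' Signed per-bin difference between two normalized histograms
#'
#' Subtracts the control histogram from the condition histogram bin by bin
#' after unit normalization. The differences sum to zero by construction.
#'
#' @param h_cond,h_ctrl Histograms on identical bin edges.
#' @return List of class `histogram_difference`: `edges`, `centers`, `diff`.
#' @export
histogram_difference <- function(h_cond, h_ctrl) {
  stopifnot(inherits(h_cond, "log_histogram"), inherits(h_ctrl, "log_histogram"))
  if (length(h_cond$edges) != length(h_ctrl$edges) ||
      any(abs(h_cond$edges - h_ctrl$edges) >
          1e-9 * pmax(h_cond$edges, h_ctrl$edges)))
    stop("histogram bin edges do not match")
  a <- normalize_histogram(h_cond)
  b <- normalize_histogram(h_ctrl)
  structure(list(edges = a$edges, centers = a$centers,
                 diff = a$counts - b$counts),
            class = "histogram_difference")
}

#' Enrichment integral of a histogram difference over an area interval
#'
#' Sum of the signed per-bin differences over the bins whose centers fall in
#' the interval; approximates the CDF difference between condition and
#' control across the interval.
#'
#' @param diff A [histogram_difference()].
#' @param area_interval `c(lo, hi)`.
#' @return Signed fraction.
#' @export
enrichment_integral <- function(diff, area_interval) {
  stopifnot(inherits(diff, "histogram_difference"))
  sel <- diff$centers >= area_interval[1] & diff$centers <= area_interval[2]
  sum(diff$diff[sel])
}

#' Least-squares log-normal fit to histogram points
#'
#' Fits `scale * dlnorm(x, meanlog, sdlog)` to the (bin center, bin value)
#' points of a histogram (the binned-curve fitting used for endosome size
#' and intensity distributions), or bins a raw sample first.
#'
#' @param x A `log_histogram`, or a positive sample which is then binned
#'   with [log_binned_histogram()] and density-normalized.
#' @param n_bins Bins used when `x` is a raw sample.
#' @return List with `meanlog`, `sdlog`, `scale`, `residual_norm`, and
#'   `fitted` values at the bin centers.
#' @export
fit_lognormal <- function(x, n_bins = 40) {
  if (inherits(x, "log_histogram")) {
    h <- x
    y <- h$counts
    if (!h$normalized) {
      widths <- diff(h$edges)
      y <- y / sum(y) / widths  # density scale
    } else {
      y <- y / diff(h$edges)
    }
  } else {
    h <- log_binned_histogram(x, n_bins)
    y <- h$counts / sum(h$counts) / diff(h$edges)
  }
  if (sum(y > 0) < 5) stop("need at least 5 nonzero bins for a fit")
  ctr <- h$centers
  # moment-based start on the implied sample
  w <- pmax(y, 0) * diff(h$edges)
  mu0 <- sum(w * log(ctr)) / sum(w)
  s0 <- sqrt(max(sum(w * (log(ctr) - mu0)^2) / sum(w), 1e-4))
  fit <- minpack.lm::nlsLM(
    y ~ scale * stats::dlnorm(ctr, meanlog, sdlog),
    start = list(meanlog = mu0, sdlog = s0, scale = 1),
    lower = c(-Inf, 1e-6, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200),
    data = data.frame(ctr = ctr, y = y))
  cf <- stats::coef(fit)
  fitted_y <- cf[["scale"]] * stats::dlnorm(ctr, cf[["meanlog"]], cf[["sdlog"]])
  rn <- sqrt(sum((y - fitted_y)^2))
  list(meanlog = cf[["meanlog"]], sdlog = cf[["sdlog"]], scale = cf[["scale"]],
       residual_norm = rn,
       relative_residual = rn / sqrt(sum(y^2)),
       fitted = fitted_y, centers = ctr, y = y)
}

#' Two-component signed log-normal fit
#'
#' Fits `A1 * dlnorm(x, m1, s1) + A2 * dlnorm(x, m2, s2)` with amplitudes of
#' either sign, for difference curves with a depletion and an enrichment
#' lobe. Multi-start over lobe locations.
#'
#' @param centers Abscissae (e.g. histogram bin centers), positive.
#' @param values Curve values (may be negative).
#' @return List with `components` (data.frame amplitude/meanlog/sdlog sorted
#'   by meanlog), `residual_norm`, `fitted`.
#' @export
fit_two_lognormal <- function(centers, values) {
  stopifnot(length(centers) == length(values), all(centers > 0))
  lx <- log(centers)
  i_min <- which.min(values); i_max <- which.max(values)
  starts <- list(
    c(m1 = lx[i_min], m2 = lx[i_max]),
    c(m1 = stats::quantile(lx, 0.25)[[1]], m2 = stats::quantile(lx, 0.75)[[1]])
  )
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nlsLM(
      values ~ A1 * stats::dlnorm(centers, m1, s1) +
        A2 * stats::dlnorm(centers, m2, s2),
      start = list(A1 = values[i_min] / stats::dlnorm(exp(st[["m1"]]), st[["m1"]], 0.4),
                   m1 = st[["m1"]], s1 = 0.4,
                   A2 = values[i_max] / stats::dlnorm(exp(st[["m2"]]), st[["m2"]], 0.4),
                   m2 = st[["m2"]], s2 = 0.4),
      lower = c(-Inf, -Inf, 1e-3, -Inf, -Inf, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 300),
      data = data.frame(centers = centers, values = values)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rn <- sqrt(sum(stats::resid(fit)^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) stop("two-component log-normal fit failed to converge")
  cf <- stats::coef(best$fit)
  comp <- data.frame(amplitude = c(cf[["A1"]], cf[["A2"]]),
                     meanlog = c(cf[["m1"]], cf[["m2"]]),
                     sdlog = c(cf[["s1"]], cf[["s2"]]))
  comp <- comp[order(comp$meanlog), ]
  rownames(comp) <- NULL
  list(components = comp, residual_norm = best$rn,
       fitted = stats::predict(best$fit))
}

# area of intersection of two discs with radii r1, r2 and center distance d
lens_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - a3
}

#' Colocalization by cross-sectional disc overlap
#'
#' Objects are modelled as discs of their measured cross-sectional area
#' centered at their (x, y) positions; a pair colocalizes when the
#' intersection area exceeds the threshold fraction of the smaller disc
#' (strictly greater). Matching is per image. Returns both the object-count
#' fraction (matched objects of `a` over all objects of `a`) and the
#' intensity-weighted fraction when an intensity column is named.
#'
#' @param records_a,records_b Object tables with `image_id, x, y, area_um2`.
#' @param overlap_threshold Fraction of the smaller cross-section, in (0, 1).
#' @param intensity_col Optional intensity column of `records_a` for the
#'   intensity-weighted fraction.
#' @return List with `fraction`, `fraction_intensity` (NA when no column
#'   given), `matched` (logical per row of `records_a`), `pairs`
#'   (data.frame of matched row indices).
#' @export
colocalization_fraction <- function(records_a, records_b,
                                    overlap_threshold = 0.30,
                                    intensity_col = NULL) {
  if (overlap_threshold <= 0 || overlap_threshold >= 1)
    stop("overlap_threshold must be in (0, 1)")
  need <- c("image_id", "x", "y", "area_um2")
  stopifnot(all(need %in% names(records_a)), all(need %in% names(records_b)))
  na <- nrow(records_a)
  matched <- logical(na)
  pairs <- list()
  ra <- sqrt(records_a$area_um2 / pi)
  rb <- sqrt(records_b$area_um2 / pi)
  for (img in unique(records_a$image_id)) {
    ia <- which(records_a$image_id == img)
    ib <- which(records_b$image_id == img)
    if (!length(ib)) next
    for (i in ia) {
      d <- sqrt((records_b$x[ib] - records_a$x[i])^2 +
                (records_b$y[ib] - records_a$y[i])^2)
      cand <- ib[d < ra[i] + rb[ib]]
      for (j in cand) {
        dd <- sqrt((records_b$x[j] - records_a$x[i])^2 +
                   (records_b$y[j] - records_a$y[i])^2)
        ov <- lens_area(ra[i], rb[j], dd) / (pi * min(ra[i], rb[j])^2)
        if (ov > overlap_threshold) {
          matched[i] <- TRUE
          pairs[[length(pairs) + 1]] <- data.frame(a = i, b = j, overlap = ov)
        }
      }
    }
  }
  frac_int <- NA_real_
  if (!is.null(intensity_col)) {
    w <- records_a[[intensity_col]]
    frac_int <- if (sum(w) > 0) sum(w[matched]) / sum(w) else NA_real_
  }
  list(fraction = if (na > 0) mean(matched) else NA_real_,
       fraction_intensity = frac_int,
       matched = matched,
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(a = integer(), b = integer(), overlap = numeric()))
}

#' Bi-exponential time-course fit
#'
#' Weighted least squares of `A * exp(-t/tau1) + B * exp(-t/tau2)` (one term
#' for growth, one for decline; rise-then-decay curves have opposite-sign
#' amplitudes). Weights are `1/sem^2` when SEMs are supplied. Multi-start
#' over 16 log-spaced time-constant pairs. The component whose amplitude is
#' positive (the late-time decay toward zero from above) is labelled the
#' decline term and its time constant reported as `tau_decay`; when both
#' amplitudes share a sign the slower constant is taken.
#'
#' @param times Time points (min), at least 5.
#' @param values Observed values.
#' @param sems Optional SEMs (`> 0`) used as weights.
#' @return List of class `biexp_fit` with `A`, `tau1` (growth), `B`, `tau2`
#'   (decline), `tau_decay`, `residual_norm`, `reliable` (FALSE when the
#'   decline amplitude is negligible, e.g. monotone rising data), `fitted`.
#' @export
fit_timecourse <- function(times, values, sems = NULL) {
  n <- length(times)
  if (n < 5) stop("need at least 5 time points")
  stopifnot(length(values) == n)
  w <- if (is.null(sems)) rep(1, n) else {
    if (any(sems <= 0)) stop("sems must be > 0 to be used as weights")
    1 / sems^2
  }
  span <- max(times[times > 0])
  taus <- exp(seq(log(span / 50), log(2 * span), length.out = 4))
  best <- NULL
  df <- data.frame(times = times, values = values)
  for (t1 in taus) for (t2 in taus) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      values ~ A * exp(-times / tau1) + B * exp(-times / tau2),
      start = list(A = -max(abs(values)), tau1 = t1,
                   B = max(abs(values)), tau2 = t2),
      lower = c(-Inf, 1e-3, -Inf, 1e-3),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200),
      data = df)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rn <- sum(w * stats::resid(fit)^2)
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) stop("bi-exponential fit failed from all starts")
  # single-exponential candidate: pure decays are a degenerate optimum of
  # the bi-exponential model (any amplitude split of one time constant), so
  # prefer the parsimonious solution when it fits as well
  for (t2 in taus) {
    fit1 <- try(suppressWarnings(minpack.lm::nlsLM(
      values ~ B * exp(-times / tau2),
      start = list(B = max(abs(values)), tau2 = t2),
      lower = c(-Inf, 1e-3), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200),
      data = df)), silent = TRUE)
    if (inherits(fit1, "try-error")) next
    rn1 <- sum(w * stats::resid(fit1)^2)
    if (rn1 <= best$rn * (1 + 1e-6) || rn1 < 1e-20) {
      c1 <- stats::coef(fit1)
      best <- list(fit = fit1, rn = rn1, single = TRUE,
                   coef = c(A = 0, tau1 = c1[["tau2"]],
                            B = c1[["B"]], tau2 = c1[["tau2"]]))
    }
  }
  cf <- if (!is.null(best$single)) best$coef else stats::coef(best$fit)
  amp <- c(cf[["A"]], cf[["B"]])
  tau <- c(cf[["tau1"]], cf[["tau2"]])
  scale_ref <- max(abs(values))
  # identify the decline component: positive amplitude (decays toward 0 from
  # above at late times). Components with negligible amplitude are ignored;
  # when both candidates share a sign the slower constant is the decline.
  live <- abs(amp) > 1e-6 * scale_ref
  decline <- if (sum(live) == 1) {
    which(live)
  } else if (xor(amp[1] > 0, amp[2] > 0)) {
    which(amp > 0)
  } else {
    which.max(tau)
  }
  growth <- 3L - decline
  A <- amp[growth]; tau1 <- tau[growth]
  B <- amp[decline]; tau2 <- tau[decline]
  # a "decline" slower than the observation window was never actually seen
  reliable <- B > 0.05 * scale_ref && tau2 <= 2 * span
  structure(list(A = A, tau1 = tau1, B = B, tau2 = tau2,
                 tau_decay = tau2,
                 residual_norm = best$rn,
                 reliable = reliable,
                 fitted = stats::predict(best$fit)),
            class = "biexp_fit")
}
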