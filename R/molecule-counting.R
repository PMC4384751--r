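# Single-fluorophore intensity calibration from photobleaching series.
#
# Frame-to-frame intensity changes (dI) of tracked objects are pooled into a
# histogram binned symmetrically about zero. Intensity fluctuations are
# symmetric, bleaching is not: the neg-double-difference (NDD) function
# freq(-dI) - freq(+dI) cancels the symmetric part and exposes the discrete
# structure of bleaching as positive peaks at 1, 2, 3, ... times the
# single-fluorophore unit intensity.

#' Frame-to-frame intensity-change histogram
#'
#' Pools dI = intensity(frame k+1) - intensity(frame k) over all objects and
#' consecutive frame pairs, and bins the values symmetrically about 0 (bin
#' centers at 0, +-w, +-2w, ...).
#'
#' @param tracks Data.frame with columns `object_id, frame, intensity`.
#'   Objects with a single frame are skipped (their number is reported in
#'   the `n_skipped` attribute with a warning).
#' @param bin_width Bin width in a.u.; default is the Freedman-Diaconis
#'   width computed on `|dI|`.
#' @return List of class `delta_histogram` with `centers`, `counts`,
#'   `bin_width`, `n_events`.
#' @export
delta_intensity_histogram <- function(tracks, bin_width = NULL) {
  stopifnot(all(c("object_id", "frame", "intensity") %in% names(tracks)))
  tracks <- tracks[order(tracks$object_id, tracks$frame), ]
  spl <- split(tracks$intensity, tracks$object_id)
  single <- sum(vapply(spl, function(v) length(v) < 2, logical(1)))
  if (single > 0)
    warning(single, " single-frame track(s) skipped")
  di <- unlist(lapply(spl, function(v) if (length(v) >= 2) diff(v)), use.names = FALSE)
  if (!length(di)) stop("no frame pairs available")
  if (is.null(bin_width)) {
    a <- abs(di)
    bin_width <- 2 * stats::IQR(a) / length(a)^(1 / 3)
    if (bin_width <= 0) bin_width <- max(1e-8, max(a) / 50, 1e-8)
  }
  k <- round(di / bin_width)
  kmax <- max(abs(k))
  counts <- tabulate(k + kmax + 1L, nbins = 2L * kmax + 1L)
  structure(list(centers = (-kmax:kmax) * bin_width, counts = counts,
                 bin_width = bin_width, n_events = length(di)),
            class = "delta_histogram")
}

#' Neg-double-difference function
#'
#' For each positive bin center dI, the difference between the counts of
#' negative and positive intensity changes of equal magnitude:
#' `value(dI) = count(-dI) - count(+dI)`. Symmetric fluctuations cancel;
#' bleaching leaves positive peaks at multiples of the single-fluorophore
#' unit intensity.
#'
#' @param hist A [delta_intensity_histogram()].
#' @return Data.frame of class `ndd_curve` with columns `delta` (positive
#'   bin centers) and `value`; carries the bin width as attribute.
#' @export
neg_double_difference <- function(hist) {
  stopifnot(inherits(hist, "delta_histogram"))
  kmax <- (length(hist$counts) - 1L) / 2L
  if (kmax < 1) stop("histogram has no nonzero bins away from 0")
  mid <- kmax + 1L
  neg <- hist$counts[(mid - 1L):1L]
  pos <- hist$counts[(mid + 1L):(2L * kmax + 1L)]
  out <- data.frame(
    delta = hist$centers[(mid + 1L):(2L * kmax + 1L)],
    value = neg - pos,
    # events entering each paired bin; under pure (symmetric) fluctuations
    # the NDD value is a difference of two Poisson counts with variance
    # neg + pos, which detect_unit_intensity() uses as the null SD
    total = neg + pos
  )
  attr(out, "bin_width") <- hist$bin_width
  class(out) <- c("ndd_curve", "data.frame")
  out
}

#' Detect the single-fluorophore unit intensity
#'
#' Smooths the NDD curve with a 3-bin moving average and returns the
#' location of the first significant local maximum as the unit intensity;
#' later peaks (expected near 2u, 3u, ...) are reported for sanity checking.
#' Significance: the smoothed value must exceed `prominence_factor` times
#' its null sampling SD — under symmetric fluctuations each NDD bin is a
#' difference of two Poisson counts with variance equal to their sum, so
#' the smoothed null SD is `sqrt(sum of window counts) / window`.
#'
#' @param ndd An [neg_double_difference()] curve with at least 10 bins.
#' @param prominence_factor Significance multiple of the null SD (3 = the
#'   conventional 3-sigma detection threshold).
#' @return List with `unit_intensity`, `peaks` (data.frame delta/value for
#'   all significant maxima), and `noise_sd` (null SD at the first peak).
#' @export
detect_unit_intensity <- function(ndd, prominence_factor = 3) {
  stopifnot(inherits(ndd, "ndd_curve"))
  n <- nrow(ndd)
  if (n < 10) stop("NDD curve must have at least 10 bins")
  v <- ndd$value
  smooth3 <- function(x, fill) {
    s <- stats::filter(x, rep(1 / 3, 3), sides = 2)
    s[1] <- fill(x[1:2]); s[n] <- fill(x[(n - 1):n])
    as.numeric(s)
  }
  s <- smooth3(v, mean)
  # null SD of the smoothed value: Poisson counting noise over the window
  se <- sqrt(smooth3(ndd$total, mean) / 3)
  se <- pmax(se, .Machine$double.eps)
  half_bin <- attr(ndd, "bin_width") / 2
  # edge bins cannot be certified as local maxima
  is_max <- vapply(seq_len(n), function(i) {
    i > 1 && i < n && s[i] >= s[i - 1] && s[i] >= s[i + 1] &&
      ndd$delta[i] > half_bin
  }, logical(1))
  sig <- which(is_max & s > prominence_factor * se)
  # collapse runs of adjacent flagged bins (smoothing plateaus) to the bin
  # with the largest raw value in each run
  if (length(sig) > 1) {
    runs <- split(sig, cumsum(c(1, diff(sig) > 1)))
    sig <- vapply(runs, function(ix) ix[which.max(v[ix])], integer(1))
  }
  if (!length(sig))
    stop("no significant peak in the NDD curve; cannot estimate the unit intensity")
  list(unit_intensity = ndd$delta[sig[1]],
       peaks = data.frame(delta = ndd$delta[sig], value = s[sig]),
       noise_sd = se[sig[1]])
}

#' Convert integral intensity to molecule count
#'
#' `count = round(intensity / u * expression_ratio * antibody_scale)`.
#' For GFP-derived counts apply the endogenous/tagged expression ratio; for
#' antibody-derived counts apply the antibody labelling scale factor (set
#' the inapplicable factor to 1). Rounding is to the nearest integer, which
#' is unbiased under symmetric intensity noise; population means should be
#' computed before rounding.
#'
#' @param integral_intensity Object intensity (a.u.), vectorized.
#' @param u Single-fluorophore unit intensity (a.u.), `> 0`.
#' @param expression_ratio Endogenous-to-tagged expression correction
#'   (e.g. 1.29 for EGFR-GFP BAC cells); `>= 1` or exactly 1 to disable.
#' @param antibody_scale Antibody labelling stoichiometry correction
#'   (e.g. 1.9); `>= 1` or exactly 1 to disable.
#' @return Integer molecule counts.
#' @export
count_molecules <- function(integral_intensity, u, expression_ratio = 1,
                            antibody_scale = 1) {
  if (u <= 0) stop("unit intensity u must be > 0")
  if (expression_ratio < 1 || antibody_scale < 1)
    stop("correction factors must be >= 1 (use 1 to disable)")
  round(integral_intensity / u * expression_ratio * antibody_scale)
}

#' Number of endocytic vesicles needed to deliver an endosome's receptors
#'
#' Nearest-integer ratio of molecules per endosome to molecules per vesicle
#' (e.g. 102 molecules per EEA1-positive endosome at 8.5 molecules per
#' diffraction-limited vesicle gives 12 vesicles).
#'
#' @param molecules_per_endosome Mean molecules per endosome.
#' @param molecules_per_vesicle Mean molecules per vesicle, `> 0`.
#' @return Integer vesicle count.
#' @export
vesicles_required <- function(molecules_per_endosome, molecules_per_vesicle) {
  if (molecules_per_vesicle <= 0) stop("molecules_per_vesicle must be > 0")
  round(molecules_per_endosome / molecules_per_vesicle)
}

#' Geometric packing capacity of a vesicle membrane
#'
#' Upper bound on the number of receptor units whose footprints fit the
#' spherical shell at radius (vesicle diameter / 2 - luminal protrusion).
#' `square-lattice-on-sphere` divides the shell area by the square of the
#' unit diameter; `disc-area-on-sphere` divides by the unit's disc area
#' (a looser bound since discs cannot tile). The result is an idealized
#' upper limit: real vesicles carry multiple cargo species.
#'
#' @param vesicle_diameter_nm Outer vesicle diameter (nm), e.g. 90 for an
#'   uncoated clathrin-derived vesicle.
#' @param luminal_protrusion_nm Luminal extent of the receptor (nm).
#' @param unit_diameter_nm Footprint diameter of the packed unit (nm),
#'   e.g. 15 for a receptor dimer.
#' @param packing_model `"square-lattice-on-sphere"` or
#'   `"disc-area-on-sphere"`.
#' @return List with `capacity` (integer units), `shell_radius_nm`,
#'   `shell_area_nm2` and `packing_model`.
#' @export
vesicle_packing_capacity <- function(vesicle_diameter_nm,
                                     luminal_protrusion_nm,
                                     unit_diameter_nm,
                                     packing_model = c("square-lattice-on-sphere",
                                                       "disc-area-on-sphere")) {
  packing_model <- match.arg(packing_model)
  if (vesicle_diameter_nm <= 0 || unit_diameter_nm <= 0 ||
      luminal_protrusion_nm < 0)
    stop("geometry must be positive")
  radius <- vesicle_diameter_nm / 2 - luminal_protrusion_nm
  if (radius <= 0) stop("luminal protrusion must be smaller than the radius")
  area <- 4 * pi * radius^2
  footprint <- switch(packing_model,
    `square-lattice-on-sphere` = unit_diameter_nm^2,
    `disc-area-on-sphere` = pi * (unit_diameter_nm / 2)^2)
  list(capacity = max(1L, as.integer(floor(area / footprint))),
       shell_radius_nm = radius, shell_area_nm2 = area,
       packing_model = packing_model)
}
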