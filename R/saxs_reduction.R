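# Reduction of 2D powder detector images: azimuthal averaging, iterative
# clipping background estimation, Bragg peak picking and conversion to
# interplanar distances.

#' Azimuthal (polar-angle) average of a detector image
#'
#' Pixels are binned by their scattering angle
#' \eqn{2\theta = \arctan(r/D)} (r = radial detector distance from the beam
#' centre, D = sample-detector distance) and each bin takes the mean (or
#' median) of its unmasked pixels. Bins containing no pixel are marked
#' invalid (`NA`) rather than zero, and interpolated linearly only to keep
#' the output a valid curve; their positions are reported in the
#' `invalid_bins` attribute.
#'
#' @param image A [detector_image()].
#' @param n_bins Number of equal-width 2-theta bins (>= 8, default 512).
#' @param statistic `"mean"` (default) or `"median"`.
#' @return A [curve1d()] in degrees 2-theta with attributes
#'   `n_pixels` (contributing pixels per bin) and `invalid_bins`
#'   (indices of empty bins).
#' @export
azimuthal_average <- function(image, n_bins = 512, statistic = c("mean", "median")) {
  stopifnot(inherits(image, "detector_image"))
  statistic <- match.arg(statistic)
  if (n_bins < 8L) stop("azimuthal_average: n_bins must be >= 8")
  geo <- image$geometry
  n_row <- nrow(image$counts); n_col <- ncol(image$counts)
  px <- matrix(rep(seq_len(n_col), each = n_row), nrow = n_row)
  py <- matrix(rep(seq_len(n_row), times = n_col), nrow = n_row)
  r_mm <- sqrt((px - geo$beam_center[1])^2 + (py - geo$beam_center[2])^2) *
    geo$pixel_size
  tt <- atan(r_mm / geo$sample_detector_distance) * 180 / pi
  use <- if (is.null(image$mask)) rep(TRUE, length(tt)) else !as.vector(image$mask)
  if (!any(use)) stop("azimuthal_average: all pixels are masked")
  tt_u <- as.vector(tt)[use]
  cts <- as.vector(image$counts)[use]
  edges <- seq(min(tt_u), max(tt_u), length.out = n_bins + 1L)
  bin <- findInterval(tt_u, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L; bin[bin > n_bins] <- n_bins
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  stat_fun <- if (statistic == "mean") mean else stats::median
  y <- rep(NA_real_, n_bins)
  agg <- tapply(cts, bin, stat_fun)
  y[as.integer(names(agg))] <- agg
  npix <- rep(0L, n_bins)
  cnt <- table(bin)
  npix[as.integer(names(cnt))] <- as.integer(cnt)
  invalid <- which(is.na(y))
  if (length(invalid) == n_bins)
    stop("azimuthal_average: no valid bin")
  if (length(invalid) > 0L)
    y[invalid] <- stats::approx(centers[-invalid], y[-invalid],
                                xout = centers[invalid], rule = 2)$y
  out <- curve1d(centers, pmax(y, 0), unit = "two_theta_deg",
                 wavelength = geo$wavelength)
  attr(out, "n_pixels") <- npix
  attr(out, "invalid_bins") <- invalid
  out
}

#' Estimate the smooth background of a powder curve by iterative clipping
#'
#' SNIP-style baseline: each sample is repeatedly replaced by the minimum of
#' itself and the average of its two neighbours `window` bins away
#' (mirrored at the edges). Peaks are clipped away while a smooth decaying
#' background is preserved; the baseline never exceeds the curve and the
#' operator is idempotent once converged.
#'
#' @param curve A [curve1d()].
#' @param window Half-width of the clipping window in bins (>= 3 and
#'   smaller than the curve length; default 15).
#' @param iterations Maximum number of clipping passes (default 200);
#'   iteration stops early once a pass no longer changes the baseline.
#' @return A [curve1d()] holding the baseline on the same grid.
#' @export
estimate_background <- function(curve, window = 15, iterations = 200) {
  stopifnot(inherits(curve, "curve1d"))
  n <- length(curve$y)
  window <- as.integer(window)
  if (window < 3L) stop("estimate_background: window must be >= 3 bins")
  if (window >= n) stop("estimate_background: window must be smaller than the curve")
  y <- curve$y
  # only interior samples with both neighbours in range are clipped; the
  # first/last `window` samples stay on the curve (documented limitation:
  # peaks closer than `window` bins to an end are not separated)
  interior <- (window + 1L):(n - window)
  tol <- 1e-12 * max(abs(y), 1e-300)
  for (it in seq_len(iterations)) {
    clipped <- pmin(y[interior],
                    (y[interior - window] + y[interior + window]) / 2)
    delta <- max(abs(clipped - y[interior]))
    y[interior] <- clipped
    if (delta < tol) break
  }
  curve1d(curve$x, y, unit = curve$unit, wavelength = curve$wavelength)
}

#' Pick Bragg peaks from a background-subtracted powder curve
#'
#' Local maxima of `curve - baseline` above a prominence floor, refined by
#' 3-point parabolic interpolation and converted to q and d via
#' [bragg_convert()]. If `expected_sigma` is supplied, a peak whose measured
#' Gaussian width (from the log-intensity curvature at the apex) exceeds
#' `(1 + width_tolerance)` times the expectation is flagged as possibly
#' blended (unresolved overlap).
#'
#' @param curve A [curve1d()] in degrees 2-theta with wavelength metadata.
#' @param baseline A [curve1d()] on the same grid (e.g. from
#'   [estimate_background()]), or `NULL` for none.
#' @param min_prominence Peak floor as a fraction of the curve's maximum
#'   intensity (default 0.02).
#' @param expected_sigma Optional expected Gaussian peak sigma (degrees).
#' @param width_tolerance Relative width excess that triggers the blended
#'   flag (default 0.02).
#' @return Object of class `peak_list`: data frame with columns
#'   `two_theta_deg`, `q_inv_angstrom`, `d_angstrom`, `height`,
#'   `prominence`, `possibly_blended`, sorted by descending d.
#' @export
pick_peaks <- function(curve, baseline = NULL, min_prominence = 0.02,
                       expected_sigma = NULL, width_tolerance = 0.02) {
  stopifnot(inherits(curve, "curve1d"))
  if (curve$unit != "two_theta_deg")
    stop("pick_peaks: curve must be on a two_theta_deg grid")
  if (is.na(curve$wavelength))
    stop("pick_peaks: curve carries no wavelength; cannot convert to d")
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "curve1d"))
    if (length(baseline$y) != length(curve$y) ||
        max(abs(baseline$x - curve$x)) > 1e-9)
      stop("pick_peaks: baseline must share the curve's grid")
  }
  res <- curve$y - if (is.null(baseline)) 0 else baseline$y
  n <- length(res)
  # floor relative to the raw curve maximum: a pure-noise residual whose
  # spikes are small against the overall signal yields no peak
  floor_h <- min_prominence * max(curve$y)
  out <- data.frame(two_theta_deg = numeric(0), q_inv_angstrom = numeric(0),
                    d_angstrom = numeric(0), height = numeric(0),
                    prominence = numeric(0), possibly_blended = logical(0))
  if (max(res) <= 0) {
    class(out) <- c("peak_list", "data.frame")
    return(out)
  }
  dx <- curve$x[2] - curve$x[1]
  is_max <- c(FALSE, res[2:(n - 1)] > res[1:(n - 2)] & res[2:(n - 1)] >= res[3:n],
              FALSE)
  for (i in which(is_max & res > floor_h)) {
    y1 <- res[i - 1L]; y2 <- res[i]; y3 <- res[i + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) > .Machine$double.eps) 0.5 * (y1 - y3) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    # ties broken toward larger d = smaller 2-theta
    tt <- curve$x[i] + delta * dx
    height <- y2 - 0.25 * (y1 - y3) * delta
    # prominence: drop to the highest flanking valley
    lo <- i; while (lo > 1L && res[lo - 1L] <= res[lo]) lo <- lo - 1L
    hi <- i; while (hi < n && res[hi + 1L] <= res[hi]) hi <- hi + 1L
    prom <- height - max(res[lo], res[hi])
    blended <- FALSE
    if (!is.null(expected_sigma) && y1 > 0 && y2 > 0 && y3 > 0) {
      # Gaussian width from curvature of log intensity at the apex
      curv <- (log(y1) - 2 * log(y2) + log(y3)) / dx^2
      if (curv < 0) {
        sig_meas <- 1 / sqrt(-curv)
        blended <- sig_meas > (1 + width_tolerance) * expected_sigma
      }
    }
    out <- rbind(out, data.frame(
      two_theta_deg = tt,
      q_inv_angstrom = bragg_convert(tt, "two_theta_deg", "q_inv_angstrom",
                                     curve$wavelength),
      d_angstrom = bragg_convert(tt, "two_theta_deg", "d_angstrom",
                                 curve$wavelength),
      height = height, prominence = prom, possibly_blended = blended))
  }
  out <- out[order(-out$d_angstrom), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Reduce a detector image to a Bragg peak list
#'
#' Composition of the three reduction stages:
#' [azimuthal_average()] -> [estimate_background()] -> [pick_peaks()].
#'
#' @param image A [detector_image()].
#' @param n_bins Bins for the azimuthal average.
#' @param window,iterations Background-estimation parameters.
#' @param min_prominence Peak-picking floor.
#' @param expected_sigma Optional expected peak sigma (degrees), see
#'   [pick_peaks()].
#' @return A `peak_list` (see [pick_peaks()]) with the intermediate curve
#'   and baseline attached as attributes `curve` and `baseline`.
#' @export
reduce_image <- function(image, n_bins = 512, window = 15, iterations = 200,
                         min_prominence = 0.02, expected_sigma = NULL) {
  curve <- azimuthal_average(image, n_bins = n_bins)
  baseline <- estimate_background(curve, window = window,
                                  iterations = iterations)
  peaks <- pick_peaks(curve, baseline, min_prominence = min_prominence,
                      expected_sigma = expected_sigma)
  attr(peaks, "curve") <- curve
  attr(peaks, "baseline") <- baseline
  peaks
}
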