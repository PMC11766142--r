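# Synthetic 1D scattering curves, powder-ring detector images and
# projection images with known ground truth.

#' One-dimensional scattering curve
#'
#' @param x Strictly increasing abscissa grid.
#' @param y Non-negative intensities, same length as `x`.
#' @param unit Abscissa unit: `"two_theta_deg"` or `"q_inv_angstrom"`.
#' @param wavelength Wavelength metadata in angstroms (may be `NA`).
#' @return Object of class `curve1d`.
#' @export
curve1d <- function(x, y, unit = c("two_theta_deg", "q_inv_angstrom"),
                    wavelength = NA_real_) {
  unit <- match.arg(unit)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("curve1d: x and y must have equal length")
  if (length(x) < 2L) stop("curve1d: at least two samples required")
  if (any(diff(x) <= 0)) stop("curve1d: abscissa must be strictly increasing")
  if (any(!is.finite(x))) stop("curve1d: abscissa must be finite")
  if (any(y < 0, na.rm = TRUE)) stop("curve1d: intensities must be >= 0")
  structure(list(x = x, y = y, unit = unit, wavelength = wavelength),
            class = "curve1d")
}

#' @export
print.curve1d <- function(x, ...) {
  cat(sprintf("curve1d: %d samples, %s in [%.4g, %.4g], lambda = %s A\n",
              length(x$x), x$unit, min(x$x), max(x$x),
              if (is.na(x$wavelength)) "NA" else format(x$wavelength)))
  invisible(x)
}

#' 2D powder detector image
#'
#' @param counts Numeric matrix of pixel intensities (rows = y, cols = x).
#' @param geometry A [scattering_geometry()].
#' @param mask Optional logical matrix, `TRUE` = dead/masked pixel.
#' @return Object of class `detector_image`.
#' @export
detector_image <- function(counts, geometry, mask = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts))) stop("detector_image: intensities must be finite")
  if (!inherits(geometry, "scattering_geometry"))
    stop("detector_image: geometry must be a scattering_geometry")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(counts)))
      stop("detector_image: mask must match the raster shape")
    mask <- mask != 0
  }
  structure(list(counts = counts, geometry = geometry, mask = mask),
            class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("detector_image: %d x %d pixels, total counts %.4g\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(x$geometry)
  invisible(x)
}

#' Synthesize a 1D powder curve: smooth background + Gaussian peaks + noise
#'
#' Model of an experimental powder SAXS curve: a smooth decaying background
#' `amplitude * x^(-decay) + constant` plus Gaussian Bragg peaks, optionally
#' Poisson-resampled (counting noise; the expectation is preserved).
#'
#' @param peaks Data frame or matrix with columns `position`, `area`,
#'   `sigma` (same abscissa units as `grid`); may have zero rows.
#' @param background Numeric triple `c(amplitude, decay, constant)`.
#' @param grid Strictly increasing abscissa grid.
#' @param unit Abscissa unit, see [curve1d()].
#' @param wavelength Wavelength metadata (Angstrom).
#' @param noise Logical: apply Poisson counting noise?
#' @param seed Seed for the noise draw.
#' @return A [curve1d()].
#' @export
synthesize_powder_curve <- function(peaks, background = c(0, 0, 0), grid,
                                    unit = "two_theta_deg",
                                    wavelength = 1.542,
                                    noise = FALSE, seed = NULL) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) > 0L) {
    if (!all(c("position", "area", "sigma") %in% names(peaks)))
      stop("synthesize_powder_curve: peaks needs columns position, area, sigma")
    if (any(peaks$sigma <= 0)) stop("synthesize_powder_curve: peak sigmas must be > 0")
  }
  if (length(background) != 3L)
    stop("synthesize_powder_curve: background must be c(amplitude, decay, constant)")
  y <- background[1] * grid^(-background[2]) + background[3]
  if (any(!is.finite(y)) || any(y < 0))
    stop("synthesize_powder_curve: background is negative or non-finite on the grid")
  for (i in seq_len(nrow(peaks)))
    y <- y + peaks$area[i] * stats::dnorm(grid, peaks$position[i], peaks$sigma[i])
  if (noise)
    y <- with_local_seed(seed, stats::rpois(length(y), y))
  curve1d(grid, y, unit = unit, wavelength = wavelength)
}

#' Render a powder-ring detector image from a 1D curve
#'
#' Each pixel receives the curve value at its scattering angle
#' \eqn{2\theta = \arctan(r/D)}, where r is the radial distance from the
#' beam centre on the detector face and D the sample-detector distance;
#' the image is azimuthally symmetric by construction. Optional Poisson
#' counting noise.
#'
#' @param curve A [curve1d()] in `two_theta_deg`; must cover the detector's
#'   angular range.
#' @param geometry A [scattering_geometry()].
#' @param image_size Integer edge length in pixels (square image).
#' @param noise Logical: Poisson noise per pixel?
#' @param seed Seed for the noise draw.
#' @return A [detector_image()].
#' @export
render_detector_image <- function(curve, geometry, image_size = 512,
                                  noise = FALSE, seed = NULL) {
  stopifnot(inherits(curve, "curve1d"), inherits(geometry, "scattering_geometry"))
  if (curve$unit != "two_theta_deg")
    stop("render_detector_image: curve must be on a two_theta_deg grid")
  n <- as.integer(image_size)
  if (n < 16L) stop("render_detector_image: image_size must be >= 16")
  bc <- geometry$beam_center
  if (bc[1] < 1 || bc[1] > n || bc[2] < 1 || bc[2] > n)
    stop("render_detector_image: beam center outside the image")
  px <- matrix(rep(seq_len(n), each = n), nrow = n)   # column index = x
  py <- matrix(rep(seq_len(n), times = n), nrow = n)  # row index = y
  r_mm <- sqrt((px - bc[1])^2 + (py - bc[2])^2) * geometry$pixel_size
  tt <- atan(r_mm / geometry$sample_detector_distance) * 180 / pi
  inside <- tt >= min(curve$x) & tt <= max(curve$x)
  if (!any(inside))
    stop("render_detector_image: curve does not cover the detector's angular range")
  vals <- matrix(0, n, n)
  vals[inside] <- stats::approx(curve$x, curve$y, xout = tt[inside])$y
  if (noise)
    vals <- with_local_seed(seed,
      matrix(stats::rpois(length(vals), pmax(vals, 0)), n, n))
  detector_image(vals, geometry)
}

#' Project oligomer centres onto an image plane
#'
#' Centres are projected along a coordinate axis and splatted as Gaussian
#' blobs of width `psf_sigma` on a pixel grid: a synthetic stand-in for a
#' TEM projection of a crystal.
#'
#' @param centers A [center_set()] with at least 2 points.
#' @param view_axis `"x"`, `"y"` or `"z"`: projection direction.
#' @param pixel_size Pixel edge in angstroms (> 0).
#' @param psf_sigma Blob width in angstroms.
#' @param pad Margin around the point cloud, angstroms.
#' @return A list with `image` (matrix, row = first in-plane coordinate),
#'   `pixel_size`, `origin` (in-plane coordinates of pixel (1,1) centre)
#'   and `axes` (names of the two in-plane axes).
#' @export
generate_projection_image <- function(centers, view_axis = c("z", "x", "y"),
                                      pixel_size = 2, psf_sigma = 8,
                                      pad = 30) {
  stopifnot(inherits(centers, "center_set"))
  if (nrow(centers$points) < 2L)
    stop("generate_projection_image: at least two centres required")
  if (pixel_size <= 0) stop("generate_projection_image: pixel_size must be > 0")
  view_axis <- match.arg(view_axis)
  keep <- setdiff(c("x", "y", "z"), view_axis)
  pts <- centers$points[, keep, drop = FALSE]
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  nu <- max(17L, ceiling((hi[1] - lo[1]) / pixel_size) + 1L)
  nv <- max(17L, ceiling((hi[2] - lo[2]) / pixel_size) + 1L)
  u <- lo[1] + (seq_len(nu) - 1) * pixel_size
  v <- lo[2] + (seq_len(nv) - 1) * pixel_size
  img <- matrix(0, nu, nv)
  s <- max(psf_sigma, pixel_size / 2)
  for (i in seq_len(nrow(pts)))
    img <- img + outer(stats::dnorm(u, pts[i, 1], s),
                       stats::dnorm(v, pts[i, 2], s))
  list(image = img, pixel_size = pixel_size, origin = lo, axes = keep)
}
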