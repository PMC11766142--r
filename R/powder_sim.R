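# Powder-pattern simulation: structure factors of point-scatterer crystal
# models, Scherrer size broadening, Gaussian peak synthesis, and scoring of
# model d-spacings against an experimental peak list.

#' Structure factor magnitude squared of a scatterer set
#'
#' \eqn{F(hkl) = \sum_j w_j\, f_j(d)\, e^{2\pi i (h x_j + k y_j + l z_j)}}
#' over fractional coordinates of the sites in the cell basis, with a
#' Gaussian form factor \eqn{f_j = \exp(-2\pi^2 \sigma_j^2 / d^2)} for sites
#' of width \eqn{\sigma_j} (a point scatterer has \eqn{f_j = 1}). Returns
#' \eqn{|F|^2}; for real weights \eqn{|F(hkl)|^2 = |F(\bar h\bar k\bar l)|^2}.
#'
#' @param scatterers A [scatterer_set()] (coordinates in angstroms, in the
#'   same Cartesian frame as [cell_basis()]).
#' @param cell A [unit_cell()].
#' @param hkl Length-3 vector or n x 3 matrix of Miller indices.
#' @return `|F|^2` value(s), in squared weight units.
#' @export
structure_factor <- function(scatterers, cell, hkl) {
  stopifnot(inherits(scatterers, "scatterer_set"))
  assert_unit_cell(cell)
  vec <- is.null(dim(hkl))
  if (vec) hkl <- matrix(hkl, nrow = 1)
  hkl <- as.matrix(hkl)
  basis <- cell_basis(cell)
  frac <- t(solve(basis, t(scatterers$sites)))      # n_sites x 3
  if (any(abs(frac) > 10))
    warning("structure_factor: some scatterers lie more than 10 cells from the origin")
  d <- d_spacing(cell, hkl)
  phase <- frac %*% t(hkl)                          # n_sites x n_refl
  damp <- exp(-2 * pi^2 * outer(scatterers$width^2, 1 / d^2))
  wre <- colSums(scatterers$weight * damp * cos(2 * pi * phase))
  wim <- colSums(scatterers$weight * damp * sin(2 * pi * phase))
  out <- wre^2 + wim^2
  if (vec) out[[1]] else out
}

#' Scherrer size broadening of a powder peak
#'
#' Gaussian width of a Bragg peak from a crystallite of finite linear size:
#' FWHM (radians) = \eqn{K\lambda/(L\cos\theta)} (Scherrer), converted to
#' the standard deviation of a normal profile in degrees of 2-theta.
#'
#' @param two_theta Scattering angle 2-theta in degrees, in (0, 180).
#' @param wavelength Wavelength in angstroms.
#' @param crystallite_size Linear crystallite size L in angstroms
#'   (e.g. 2000 for a 200 nm crystal).
#' @param shape_constant Scherrer constant K (default 0.9).
#' @return Gaussian sigma in degrees of 2-theta.
#' @export
size_broadening <- function(two_theta, wavelength, crystallite_size,
                            shape_constant = 0.9) {
  if (any(two_theta <= 0) || any(two_theta >= 180))
    stop("size_broadening: two_theta must be in (0, 180) degrees")
  if (crystallite_size <= 0) stop("size_broadening: crystallite size must be > 0")
  theta <- two_theta / 2 * pi / 180
  cth <- cos(theta)
  if (any(cth < 1e-12))
    stop("size_broadening: formula diverges as theta approaches 90 degrees")
  fwhm_rad <- shape_constant * wavelength / (crystallite_size * cth)
  fwhm_deg <- fwhm_rad * 180 / pi
  fwhm_deg / (2 * sqrt(2 * log(2)))
}

#' Simulate the 1D powder diffraction pattern of a model crystal
#'
#' Enumerates all Friedel-canonical reflections with d >= `d_min`, weights
#' each by multiplicity (2, the Friedel pair) times `|F|^2` from the
#' scatterer model (optionally a Lorentz factor), places a Gaussian of
#' Scherrer width at its 2-theta, and sums. Peak positions, not absolute
#' intensities, are the quantity compared with experiment.
#'
#' @param cell A [unit_cell()].
#' @param scatterers A [scatterer_set()]; one unit cell's worth of motif is
#'   enough (a full crystal block gives the same peak positions).
#' @param wavelength Wavelength in angstroms (default 1.542).
#' @param crystallite_size Crystallite linear size in angstroms (default
#'   2000, i.e. 200 nm).
#' @param d_min Resolution limit in angstroms (default 30).
#' @param grid Abscissa grid in degrees 2-theta, or `NULL` to build one
#'   covering all reflections with margin.
#' @param lorentz Apply the powder Lorentz factor
#'   \eqn{1/(\sin\theta\,\sin 2\theta)} to intensities? Default `FALSE`.
#' @param shape_constant Scherrer constant K.
#' @return Object of class `powder_pattern`: a [curve1d()] plus provenance
#'   (`cell`, `reflections` with filled weights, `crystallite_size`,
#'   `wavelength`).
#' @export
simulate_powder_pattern <- function(cell, scatterers, wavelength = 1.542,
                                    crystallite_size = 2000, d_min = 30,
                                    grid = NULL, lorentz = FALSE,
                                    shape_constant = 0.9) {
  assert_unit_cell(cell)
  refl <- enumerate_reflections(cell, d_min)
  if (nrow(refl) == 0L) stop("simulate_powder_pattern: no reflection above d_min")
  refl$weight <- structure_factor(scatterers, cell,
                                  as.matrix(refl[, c("h", "k", "l")]))
  tt <- bragg_convert(refl$d, "d_angstrom", "two_theta_deg", wavelength)
  sig <- size_broadening(tt, wavelength, crystallite_size, shape_constant)
  area <- 2 * refl$weight                       # Friedel multiplicity
  if (lorentz) {
    th <- tt / 2 * pi / 180
    area <- area / (sin(th) * sin(2 * th))
  }
  refl$two_theta <- tt
  refl$sigma <- sig
  refl$area <- area
  if (is.null(grid)) {
    lo <- max(1e-4, min(tt) - 6 * max(sig))
    hi <- max(tt) + 6 * max(sig)
    grid <- seq(lo, hi, length.out = 4000L)
  }
  y <- rep(0, length(grid))
  for (i in seq_len(nrow(refl)))
    y <- y + area[i] * stats::dnorm(grid, tt[i], sig[i])
  # warn if the grid clips any peak by more than 3 sigma
  clipped <- tt - 3 * sig < min(grid) | tt + 3 * sig > max(grid)
  if (any(clipped)) {
    frac <- sum(area[clipped]) / sum(area)
    warning(sprintf(
      "simulate_powder_pattern: grid clips %d peak(s) by > 3 sigma (%.1f%% of intensity)",
      sum(clipped), 100 * frac))
  }
  curve <- curve1d(grid, y, unit = "two_theta_deg", wavelength = wavelength)
  structure(list(curve = curve, cell = cell, reflections = refl,
                 crystallite_size = crystallite_size,
                 wavelength = wavelength),
            class = "powder_pattern")
}

#' @export
print.powder_pattern <- function(x, ...) {
  cat(sprintf("powder_pattern: %d reflections (d >= %.3g A), L = %.4g A, lambda = %.4g A\n",
              nrow(x$reflections), min(x$reflections$d), x$crystallite_size,
              x$wavelength))
  invisible(x)
}

#' Match model d-spacings against an experimental peak list
#'
#' Greedy best-first pairing by relative difference: the closest
#' (experimental, model) pair is matched and removed, until no pair is
#' within `rel_tolerance`. Each experimental peak matches at most one model
#' d-spacing.
#'
#' @param model_d Numeric vector of model d-spacings, angstroms.
#' @param experimental_d Numeric vector of experimental d-spacings (must be
#'   non-empty).
#' @param rel_tolerance Maximum relative difference, in (0, 0.5)
#'   (default 0.05).
#' @return Object of class `peak_match`: data frame `pairs` (columns
#'   `experimental_d`, `model_d`, `rel_diff`; unmatched experimental peaks
#'   have `NA` model entries), `n_matched`, `tolerance`.
#' @export
match_peaks <- function(model_d, experimental_d, rel_tolerance = 0.05) {
  if (length(experimental_d) == 0L)
    stop("match_peaks: experimental peak list is empty")
  if (rel_tolerance <= 0 || rel_tolerance >= 0.5)
    stop("match_peaks: rel_tolerance must be in (0, 0.5)")
  ne <- length(experimental_d)
  pairs <- data.frame(experimental_d = sort(experimental_d, decreasing = TRUE),
                      model_d = NA_real_, rel_diff = NA_real_)
  if (length(model_d) > 0L) {
    avail_m <- rep(TRUE, length(model_d))
    avail_e <- rep(TRUE, ne)
    rel <- abs(outer(pairs$experimental_d, model_d, "-")) /
      matrix(pairs$experimental_d, ne, length(model_d))
    repeat {
      rel_open <- rel
      rel_open[!avail_e, ] <- Inf
      rel_open[, !avail_m] <- Inf
      best <- which.min(rel_open)
      if (!length(best) || !is.finite(rel_open[best])) break
      ij <- arrayInd(best, dim(rel))
      if (rel[ij] > rel_tolerance) break
      pairs$model_d[ij[1]] <- model_d[ij[2]]
      pairs$rel_diff[ij[1]] <- rel[ij]
      avail_e[ij[1]] <- FALSE
      avail_m[ij[2]] <- FALSE
      if (!any(avail_e) || !any(avail_m)) break
    }
  }
  structure(list(pairs = pairs, n_matched = sum(!is.na(pairs$model_d)),
                 tolerance = rel_tolerance),
            class = "peak_match")
}

#' @export
print.peak_match <- function(x, ...) {
  cat(sprintf("peak match: %d of %d experimental peaks matched (tolerance %.1f%%)\n",
              x$n_matched, nrow(x$pairs), 100 * x$tolerance))
  df <- x$pairs
  df$experimental_d <- round(df$experimental_d, 2)
  df$model_d <- round(df$model_d, 2)
  df$rel_diff <- round(df$rel_diff, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
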