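#' Triclinic unit cell
#'
#' Construct a validated triclinic (P1) unit cell. All lengths are in
#' angstroms and all angles in degrees; this is the internal convention
#' throughout the package (trigonometry is done in radians internally).
#'
#' @param a,b,c Cell edge lengths in angstroms; must be positive.
#' @param alpha,beta,gamma Inter-axial angles in degrees (`alpha` between
#'   b and c, `beta` between a and c, `gamma` between a and b); each must
#'   lie strictly between 0 and 180 and jointly satisfy the triclinic
#'   realizability condition
#'   \eqn{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma +
#'        2\cos\alpha\cos\beta\cos\gamma > 0}.
#'
#' @return An object of class `unit_cell`: a named list with elements
#'   `a`, `b`, `c`, `alpha`, `beta`, `gamma`.
#'
#' @examples
#' # the triclinic cell of the in vitro Dps-DNA crystal
#' cell <- unit_cell(83.3, 83.3, 54.2, 60.5, 60.5, 60.5)
#' cell_volume(cell)
#' @export
unit_cell <- function(a, b, c, alpha, beta, gamma) {
  for (nm in c("a", "b", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("unit_cell: edge length '", nm, "' must be a positive finite number")
  }
  for (nm in c("alpha", "beta", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v >= 180)
      stop("unit_cell: angle '", nm, "' must lie strictly between 0 and 180 degrees")
  }
  disc <- cell_discriminant(alpha, beta, gamma)
  if (disc <= 0)
    stop("unit_cell: angle combination is not geometrically realizable ",
         "(volume discriminant ", format(disc), " <= 0)")
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "unit_cell")
}

cell_discriminant <- function(alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Triclinic unit cell (P1)\n  a = %.4g  b = %.4g  c = %.4g  [Angstrom]\n",
              x$a, x$b, x$c))
  cat(sprintf("  alpha = %.4g  beta = %.4g  gamma = %.4g  [degrees]\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  volume = %.6g Angstrom^3\n", cell_volume(x)))
  invisible(x)
}

#' @export
format.unit_cell <- function(x, ...) {
  sprintf("unit_cell(a=%.6g, b=%.6g, c=%.6g, alpha=%.6g, beta=%.6g, gamma=%.6g)",
          x$a, x$b, x$c, x$alpha, x$beta, x$gamma)
}

is_unit_cell <- function(x) inherits(x, "unit_cell")

assert_unit_cell <- function(cell) {
  if (!is_unit_cell(cell)) stop("expected a 'unit_cell' object")
  invisible(cell)
}

#' Direct metric tensor of a unit cell
#'
#' The 3x3 Gram matrix \eqn{G_{ij} = v_i \cdot v_j} of the direct lattice
#' vectors, in squared angstroms. Symmetric positive definite for any valid
#' cell.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 symmetric numeric matrix.
#' @export
metric_tensor <- function(cell) {
  assert_unit_cell(cell)
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  with(cell, matrix(c(a * a,      a * b * cg, a * c * cb,
                      a * b * cg, b * b,      b * c * ca,
                      a * c * cb, b * c * ca, c * c),
                    nrow = 3, byrow = TRUE,
                    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
}

#' Cartesian basis vectors of a unit cell
#'
#' Columns are the lattice vectors a, b, c in a fixed Cartesian frame:
#' a along x, b in the xy-plane, c by the standard crystallographic
#' construction. This orientation convention makes synthetic-lattice
#' generation and structure-factor fractionalisation reproducible.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 matrix whose columns are the lattice vectors (Angstrom).
#' @export
cell_basis <- function(cell) {
  assert_unit_cell(cell)
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  av <- c(cell$a, 0, 0)
  bv <- c(cell$b * cg, cell$b * sg, 0)
  cx <- cell$c * cb
  cy <- cell$c * (ca - cb * cg) / sg
  cz2 <- cell$c^2 - cx^2 - cy^2
  if (cz2 <= 0) stop("cell_basis: degenerate cell (c vector has no out-of-plane component)")
  cv <- c(cx, cy, sqrt(cz2))
  m <- cbind(a = av, b = bv, c = cv)
  rownames(m) <- c("x", "y", "z")
  m
}

#' Unit-cell volume
#'
#' \eqn{V = abc\sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma +
#' 2\cos\alpha\cos\beta\cos\gamma}}, equal to `sqrt(det(metric_tensor(cell)))`.
#'
#' @param cell A [unit_cell()].
#' @return Volume in cubic angstroms.
#' @export
cell_volume <- function(cell) {
  assert_unit_cell(cell)
  disc <- cell_discriminant(cell$alpha, cell$beta, cell$gamma)
  if (disc <= 0) stop("cell_volume: non-realizable angle combination")
  cell$a * cell$b * cell$c * sqrt(disc)
}

#' Construct a unit cell from a 3x3 basis matrix
#'
#' Inverse of [cell_basis()] up to rigid rotation: cell constants are read
#' off the Gram matrix of the supplied column vectors.
#'
#' @param basis 3x3 matrix whose columns are lattice vectors (Angstrom).
#' @return A [unit_cell()].
#' @export
cell_from_basis <- function(basis) {
  stopifnot(is.matrix(basis), all(dim(basis) == c(3L, 3L)))
  g <- crossprod(basis)
  len <- sqrt(diag(g))
  ang <- function(i, j) acos(max(-1, min(1, g[i, j] / (len[i] * len[j])))) * 180 / pi
  unit_cell(len[1], len[2], len[3], ang(2, 3), ang(1, 3), ang(1, 2))
}

#' Interplanar spacing d(hkl)
#'
#' Perpendicular distance between (hkl) lattice planes,
#' \eqn{d = 1/\sqrt{h^T G^{-1} h}} with G the direct metric tensor.
#' Invariant under Friedel inversion (hkl) -> (-h,-k,-l), and satisfies
#' d(n h, n k, n l) = d(h,k,l)/n.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer Miller indices: a length-3 vector or an n x 3 matrix.
#' @return d-spacing(s) in angstroms.
#' @export
d_spacing <- function(cell, hkl) {
  assert_unit_cell(cell)
  if (is.null(dim(hkl))) hkl <- matrix(hkl, nrow = 1)
  hkl <- as.matrix(hkl)
  if (ncol(hkl) != 3L) stop("d_spacing: hkl must have three columns")
  if (any(rowSums(hkl != 0) == 0L))
    stop("d_spacing: (0,0,0) is not a valid reflection")
  ginv <- solve(metric_tensor(cell))
  q2 <- rowSums((hkl %*% ginv) * hkl)   # h^T G^{-1} h
  d <- 1 / sqrt(q2)
  if (length(d) == 1L) d[[1]] else d
}

#' Canonicalize Miller indices to the Friedel representative
#'
#' Of each pair (hkl)/(-h,-k,-l) exactly one is kept: the one whose first
#' nonzero index is positive.
#'
#' @param hkl Length-3 vector or n x 3 matrix of integer indices.
#' @return Object of the same shape with canonical signs.
#' @export
friedel_canonical <- function(hkl) {
  vec <- is.null(dim(hkl))
  if (vec) hkl <- matrix(hkl, nrow = 1)
  hkl <- as.matrix(hkl)
  flip <- apply(hkl, 1L, function(r) {
    nz <- r[r != 0]
    length(nz) > 0L && nz[1] < 0
  })
  hkl[flip, ] <- -hkl[flip, , drop = FALSE]
  if (vec) drop(hkl) else hkl
}

#' Enumerate all reflections down to a resolution limit
#'
#' All Friedel-canonical reflections (hkl) with d >= `d_min`, sorted by
#' descending d. The index search bound per axis follows from
#' \eqn{|h| = |r^* \cdot a| \le |r^*|\,|a| \le a/d_{min}} (Cauchy-Schwarz
#' with the reciprocal vector r* of length 1/d), with one extra index of
#' safety margin.
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in angstroms (> 0).
#' @return A data frame of class `reflection_set` with columns
#'   `h`, `k`, `l`, `d`, `weight` (weight initialised to `NA`, filled by
#'   [simulate_powder_pattern()]).
#' @export
enumerate_reflections <- function(cell, d_min) {
  assert_unit_cell(cell)
  if (!is.numeric(d_min) || length(d_min) != 1L || !is.finite(d_min) || d_min <= 0)
    stop("enumerate_reflections: d_min must be a positive number")
  hmax <- floor(cell$a / d_min) + 1L
  kmax <- floor(cell$b / d_min) + 1L
  lmax <- floor(cell$c / d_min) + 1L
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  grid <- grid[rowSums(grid != 0) > 0L, , drop = FALSE]
  # keep the Friedel representative only
  keep <- apply(grid, 1L, function(r) { nz <- r[r != 0]; nz[1] > 0 })
  grid <- grid[keep, , drop = FALSE]
  d <- d_spacing(cell, grid)
  sel <- d >= d_min
  grid <- grid[sel, , drop = FALSE]
  d <- d[sel]
  ord <- order(-d, grid[, 1], grid[, 2], grid[, 3])
  out <- data.frame(h = grid[ord, 1], k = grid[ord, 2], l = grid[ord, 3],
                    d = d[ord], weight = rep(NA_real_, length(ord)),
                    row.names = NULL)
  class(out) <- c("reflection_set", "data.frame")
  out
}

#' Convert between d-spacing, scattering vector q and scattering angle
#'
#' Conversions among the three standard Bragg abscissae, using
#' \eqn{q = 4\pi \sin\theta / \lambda}, \eqn{d = 2\pi/q} and
#' \eqn{2\theta = 2\arcsin(\lambda/2d)}. Units: `"d_angstrom"` (Angstrom),
#' `"q_inv_angstrom"` (reciprocal Angstrom), `"two_theta_deg"` (degrees).
#'
#' @param value Positive numeric vector to convert.
#' @param from,to Unit names, one of `"d_angstrom"`, `"q_inv_angstrom"`,
#'   `"two_theta_deg"`.
#' @param wavelength X-ray wavelength in angstroms (required whenever
#'   `two_theta_deg` is involved).
#' @return Converted numeric vector.
#' @export
bragg_convert <- function(value, from, to, wavelength = NULL) {
  units <- c("d_angstrom", "q_inv_angstrom", "two_theta_deg")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0))
    stop("bragg_convert: values must be positive and finite")
  needs_lambda <- "two_theta_deg" %in% c(from, to)
  if (needs_lambda) {
    if (is.null(wavelength) || !is.numeric(wavelength) || wavelength <= 0)
      stop("bragg_convert: a positive wavelength is required for angle conversions")
  }
  d <- switch(from,
    d_angstrom = value,
    q_inv_angstrom = 2 * pi / value,
    two_theta_deg = {
      th <- value / 2 * pi / 180
      wavelength / (2 * sin(th))
    })
  if (to == "two_theta_deg") {
    if (any(wavelength >= 2 * d))
      stop("bragg_convert: wavelength >= 2d, reflection unreachable at this wavelength")
    2 * asin(wavelength / (2 * d)) * 180 / pi
  } else if (to == "q_inv_angstrom") {
    2 * pi / d
  } else {
    d
  }
}

#' Scattering geometry of a flat powder detector
#'
#' @param wavelength X-ray wavelength in angstroms.
#' @param sample_detector_distance Sample-to-detector distance in mm.
#' @param beam_center Length-2 vector, beam-centre pixel coordinates
#'   (x, y; may be fractional).
#' @param pixel_size Pixel edge in mm.
#' @return Object of class `scattering_geometry`.
#' @export
scattering_geometry <- function(wavelength = 1.542,
                                sample_detector_distance = 2000,
                                beam_center = c(256.5, 256.5),
                                pixel_size = 0.2) {
  stopifnot(wavelength > 0, sample_detector_distance > 0, pixel_size > 0,
            length(beam_center) == 2L, all(is.finite(beam_center)))
  structure(list(wavelength = wavelength,
                 sample_detector_distance = sample_detector_distance,
                 beam_center = as.numeric(beam_center),
                 pixel_size = pixel_size),
            class = "scattering_geometry")
}

#' @export
print.scattering_geometry <- function(x, ...) {
  cat(sprintf(paste0("Scattering geometry: lambda = %.4g A, distance = %.4g mm,\n",
                     "  beam center = (%.2f, %.2f) px, pixel = %.3g mm\n"),
              x$wavelength, x$sample_detector_distance,
              x$beam_center[1], x$beam_center[2], x$pixel_size))
  invisible(x)
}
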