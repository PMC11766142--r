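# Pair distance and pair angle distribution functions: kernel density
# estimates over inter-centre distances and neighbour-vector angles, with
# mode extraction. These are the descriptive statistics from which the
# lattice constants of a crystal of oligomer centres are read off.

# Local maxima of a KDE curve above a prominence floor, each refined by
# 3-point parabolic interpolation. Returns a data frame sorted by location.
kde_modes <- function(x, y, min_height_frac = 0.05) {
  n <- length(y)
  if (n < 3L) return(data.frame(location = numeric(0), height = numeric(0),
                                width = numeric(0), mass_fraction = numeric(0)))
  floor_h <- min_height_frac * max(y)
  is_max <- c(y[1] > y[2],
              y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              y[n] > y[n - 1])
  idx <- which(is_max & y > floor_h)
  if (length(idx) == 0L)
    return(data.frame(location = numeric(0), height = numeric(0),
                      width = numeric(0), mass_fraction = numeric(0)))
  dx <- x[2] - x[1]
  loc <- height <- width <- mass <- numeric(length(idx))
  # valley-to-valley support of each mode, for mass fractions and widths
  bounds <- vapply(idx, function(i) {
    lo <- i; while (lo > 1L && y[lo - 1L] < y[lo]) lo <- lo - 1L
    hi <- i; while (hi < n && y[hi + 1L] < y[hi]) hi <- hi + 1L
    c(lo, hi)
  }, numeric(2))
  total <- sum(y) * dx
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (i == 1L || i == n) {            # boundary mode: no refinement
      loc[j] <- x[i]
      height[j] <- y[i]
    } else {
      # parabolic refinement on (x[i-1], x[i], x[i+1])
      y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
      denom <- y1 - 2 * y2 + y3
      delta <- if (abs(denom) > .Machine$double.eps) 0.5 * (y1 - y3) / denom else 0
      delta <- max(-0.5, min(0.5, delta))
      loc[j] <- x[i] + delta * dx
      height[j] <- y2 - 0.25 * (y1 - y3) * delta
    }
    lo <- bounds[1, j]; hi <- bounds[2, j]
    seg <- lo:hi
    m <- sum(y[seg]) * dx
    mass[j] <- m / total
    # width as the sd of the mode's own segment
    mu <- sum(x[seg] * y[seg]) / sum(y[seg])
    width[j] <- sqrt(sum((x[seg] - mu)^2 * y[seg]) / sum(y[seg]))
  }
  out <- data.frame(location = loc, height = height, width = width,
                    mass_fraction = mass)
  out[order(out$location), , drop = FALSE]
}

new_distribution_modes <- function(modes, bandwidth, kind, grid_x, grid_y) {
  structure(list(modes = modes, bandwidth = bandwidth, kind = kind,
                 grid = data.frame(x = grid_x, density = grid_y)),
            class = "distribution_modes")
}

#' @export
print.distribution_modes <- function(x, ...) {
  unit <- if (x$kind == "distance") "Angstrom" else "degrees"
  cat(sprintf("%s distribution: %d mode(s), bandwidth %.3g %s\n",
              x$kind, nrow(x$modes), x$bandwidth, unit))
  if (nrow(x$modes) > 0L) {
    df <- x$modes
    df$location <- round(df$location, 2)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Pair distance distribution function of a centre set
#'
#' Kernel density estimate of all pairwise inter-centre distances up to
#' `r_max`, with modes (local maxima above a prominence floor) refined by
#' parabolic interpolation. For a crystal of oligomer centres the mode
#' locations are lattice-vector lengths (e.g. 83.3 and 54.2 Angstrom for
#' the Dps-DNA crystal).
#'
#' @param centers A [center_set()] with >= 2 points.
#' @param r_max Maximum distance considered, angstroms.
#' @param bandwidth Gaussian KDE bandwidth, angstroms (default 1.5).
#' @param min_height_frac Mode floor as a fraction of the maximum density.
#' @return A `distribution_modes` object (modes, bandwidth, KDE grid).
#' @export
pair_distance_distribution <- function(centers, r_max = 100, bandwidth = 1.5,
                                       min_height_frac = 0.05) {
  stopifnot(inherits(centers, "center_set"))
  if (nrow(centers$points) < 2L)
    stop("pair_distance_distribution: at least two centres required")
  if (r_max <= 0 || bandwidth <= 0)
    stop("pair_distance_distribution: r_max and bandwidth must be > 0")
  dd <- as.numeric(stats::dist(centers$points))
  dd <- dd[dd <= r_max]
  if (length(dd) == 0L)
    stop("pair_distance_distribution: no pair within r_max")
  kde <- stats::density(dd, bw = bandwidth, from = 0, to = r_max, n = 2048)
  new_distribution_modes(kde_modes(kde$x, kde$y, min_height_frac),
                         bandwidth, "distance", kde$x, kde$y)
}

#' Pair angle distribution function of a centre set
#'
#' For every centre, the angles between all pairs of displacement vectors
#' to its neighbours within `neighbor_cutoff` are pooled and a KDE on
#' [0, 180] degrees is formed; modes are extracted as in
#' [pair_distance_distribution()]. For the Dps-DNA crystal lattice the
#' dominant acute mode sits at the inter-axial angle (60.5 degrees).
#'
#' @param centers A [center_set()] with >= 3 points.
#' @param neighbor_cutoff Neighbour distance cutoff, angstroms.
#' @param bandwidth KDE bandwidth in degrees (default 3).
#' @param min_height_frac Mode floor as a fraction of the maximum density.
#' @return A `distribution_modes` object.
#' @export
pair_angle_distribution <- function(centers, neighbor_cutoff = 90,
                                    bandwidth = 3, min_height_frac = 0.05) {
  stopifnot(inherits(centers, "center_set"))
  pts <- centers$points
  if (nrow(pts) < 3L)
    stop("pair_angle_distribution: at least three centres required")
  if (neighbor_cutoff <= 0 || bandwidth <= 0)
    stop("pair_angle_distribution: cutoff and bandwidth must be > 0")
  angles <- angle_samples(pts, neighbor_cutoff)
  if (length(angles) == 0L)
    stop("pair_angle_distribution: no centre has two neighbours within the cutoff")
  kde <- stats::density(angles, bw = bandwidth, from = 0, to = 180, n = 1024)
  new_distribution_modes(kde_modes(kde$x, kde$y, min_height_frac),
                         bandwidth, "angle", kde$x, kde$y)
}

# All angles (degrees) between pairs of neighbour displacement vectors at a
# common centre, neighbours taken within `cutoff`.
angle_samples <- function(pts, cutoff) {
  n <- nrow(pts)
  dmat <- as.matrix(stats::dist(pts))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- which(dmat[i, ] <= cutoff & seq_len(n) != i)
    if (length(nb) < 2L) next
    v <- sweep(pts[nb, , drop = FALSE], 2, pts[i, ])
    v <- v / sqrt(rowSums(v^2))
    cosm <- tcrossprod(v)
    cosv <- cosm[upper.tri(cosm)]
    out[[i]] <- acos(pmax(-1, pmin(1, cosv))) * 180 / pi
  }
  unlist(out)
}
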