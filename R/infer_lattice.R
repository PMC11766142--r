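# Recovery of triclinic lattice constants from oligomer-centre point clouds:
# neighbour-vector clustering, least-squares basis refinement, and a
# deterministic cell-setting convention.

#' Infer P1 lattice constants from oligomer centres
#'
#' Recovers a triclinic basis from a (possibly jittered, incomplete) finite
#' lattice of centres:
#' 1. collect displacement vectors between all centre pairs closer than
#'    `neighbor_cutoff`;
#' 2. cluster them by direction and length, merging antipodal vectors
#'    (v and -v count as one lattice direction);
#' 3. take the three shortest, well non-coplanar cluster means as a basis
#'    candidate;
#' 4. refine the basis by least squares against every displacement vector,
#'    indexed to its nearest integer combination;
#' 5. re-express the lattice in the package's canonical cell setting
#'    (see [canonical_cell_setting()]).
#'
#' Per-constant uncertainties are standard deviations over the displacement
#' vectors indexed to each basis vector (cluster scatter), not fit
#' covariances.
#'
#' @param centers A [center_set()] with at least 8 points.
#' @param neighbor_cutoff Pair-distance cutoff in angstroms (default 100;
#'   must exceed the longest expected cell edge).
#' @param cluster_tolerance Clustering radius in angstroms (default 8):
#'   displacement vectors within this distance of a cluster mean (up to
#'   sign) join the cluster.
#' @param min_cluster_size Clusters with fewer members are treated as noise.
#' @return An object of class `lattice_fit`: list with `cell`
#'   ([unit_cell()]), `uncertainty` (list `lengths` in Angstrom, `angles`
#'   in degrees), `basis` (3x3, columns a, b, c), `n_neighbors_used`,
#'   `residual` (RMS, Angstrom).
#' @export
infer_lattice <- function(centers, neighbor_cutoff = 100,
                          cluster_tolerance = 8, min_cluster_size = 2) {
  stopifnot(inherits(centers, "center_set"))
  pts <- centers$points
  if (nrow(pts) < 8L) stop("infer_lattice: at least 8 centres required")
  if (neighbor_cutoff <= 0 || cluster_tolerance <= 0)
    stop("infer_lattice: cutoff and tolerance must be > 0")

  vecs <- pair_vectors(pts, neighbor_cutoff)
  if (nrow(vecs) < 3L)
    stop("infer_lattice: fewer than 3 neighbour vectors within the cutoff")

  cl <- cluster_antipodal(vecs, cluster_tolerance)
  cl <- cl[cl$n >= min_cluster_size, , drop = FALSE]
  if (nrow(cl) < 3L)
    stop("infer_lattice: fewer than 3 neighbour-vector clusters; ",
         "point set too small or too noisy")

  basis0 <- pick_basis(cl)
  if (is.null(basis0))
    stop("infer_lattice: neighbour directions are coplanar or degenerate; ",
         "cannot span a 3D lattice")

  ref <- refine_basis(basis0, vecs, max_residual = cluster_tolerance)
  setting <- canonical_cell_setting(ref$basis)
  basis <- setting$basis
  cell <- cell_from_basis(basis)

  unc <- basis_uncertainties(basis, vecs, max_residual = cluster_tolerance)

  structure(list(cell = cell,
                 uncertainty = unc$uncertainty,
                 basis = basis,
                 n_neighbors_used = ref$n_used,
                 residual = ref$residual),
            class = "lattice_fit")
}

#' @export
print.lattice_fit <- function(x, ...) {
  u <- x$uncertainty
  cat("Lattice fit (P1)\n")
  cat(sprintf("  a = %.2f +/- %.2f   b = %.2f +/- %.2f   c = %.2f +/- %.2f  [A]\n",
              x$cell$a, u$lengths[1], x$cell$b, u$lengths[2],
              x$cell$c, u$lengths[3]))
  cat(sprintf("  alpha = %.2f +/- %.2f   beta = %.2f +/- %.2f   gamma = %.2f +/- %.2f  [deg]\n",
              x$cell$alpha, u$angles[1], x$cell$beta, u$angles[2],
              x$cell$gamma, u$angles[3]))
  cat(sprintf("  %d neighbour vectors used, RMS residual %.3g A\n",
              x$n_neighbors_used, x$residual))
  invisible(x)
}

# Displacement vectors between all point pairs closer than cutoff (one per
# unordered pair).
pair_vectors <- function(pts, cutoff) {
  dmat <- as.matrix(stats::dist(pts))
  idx <- which(upper.tri(dmat) & dmat <= cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0, 3))
  pts[idx[, 2], , drop = FALSE] - pts[idx[, 1], , drop = FALSE]
}

# Greedy antipodal-aware clustering of vectors. Vectors are processed in
# order of increasing length; each joins the nearest cluster whose running
# mean is within `tol` of it (after sign alignment), else founds a new one.
cluster_antipodal <- function(vecs, tol) {
  ord <- order(sqrt(rowSums(vecs^2)))
  nmax <- nrow(vecs)
  means <- matrix(NA_real_, nmax, 3)   # running cluster means
  counts <- integer(nmax)
  k <- 0L
  tol2 <- tol^2
  for (i in ord) {
    v <- vecs[i, ]
    if (k > 0L) {
      M <- means[seq_len(k), , drop = FALSE]
      dplus <- (M[, 1] - v[1])^2 + (M[, 2] - v[2])^2 + (M[, 3] - v[3])^2
      dminus <- (M[, 1] + v[1])^2 + (M[, 2] + v[2])^2 + (M[, 3] + v[3])^2
      d2 <- pmin(dplus, dminus)
      j <- which.min(d2)
      if (d2[j] <= tol2) {
        s <- if (dplus[j] <= dminus[j]) 1 else -1
        counts[j] <- counts[j] + 1L
        means[j, ] <- means[j, ] + (s * v - means[j, ]) / counts[j]
        next
      }
    }
    k <- k + 1L
    means[k, ] <- v
    counts[k] <- 1L
  }
  mm <- means[seq_len(k), , drop = FALSE]
  data.frame(vx = mm[, 1], vy = mm[, 2], vz = mm[, 3],
             length = sqrt(rowSums(mm^2)), n = counts[seq_len(k)])
}

# Three shortest, well non-coplanar cluster means.
pick_basis <- function(cl, min_sin = 0.15, min_triple = 0.15) {
  cl <- cl[order(cl$length), , drop = FALSE]
  m <- as.matrix(cl[, c("vx", "vy", "vz")])
  n <- nrow(m)
  for (i in seq_len(n - 2L)) {
    vi <- m[i, ]
    for (j in (i + 1L):(n - 1L)) {
      vj <- m[j, ]
      cr <- c(vi[2] * vj[3] - vi[3] * vj[2],
              vi[3] * vj[1] - vi[1] * vj[3],
              vi[1] * vj[2] - vi[2] * vj[1])
      if (sqrt(sum(cr^2)) / (cl$length[i] * cl$length[j]) < min_sin) next
      for (k in (j + 1L):n) {
        vk <- m[k, ]
        tp <- abs(sum(cr * vk)) /
          (cl$length[i] * cl$length[j] * cl$length[k])
        if (tp >= min_triple) return(cbind(vi, vj, vk))
      }
    }
  }
  NULL
}

# Least-squares refinement of a basis against displacement vectors indexed
# to nearest integer combinations. Vectors whose residual exceeds
# max_residual (or that index to 0) are dropped each round.
refine_basis <- function(basis, vecs, max_residual, n_iter = 4) {
  B <- basis
  n_used <- 0L
  rms <- NA_real_
  for (it in seq_len(n_iter)) {
    N <- round(t(solve(B, t(vecs))))
    keep <- rowSums(N != 0) > 0L
    res2 <- rowSums((vecs - N %*% t(B))^2)
    keep <- keep & res2 <= max_residual^2
    if (sum(keep) < 3L)
      stop("infer_lattice: basis refinement lost all neighbour vectors")
    Nk <- N[keep, , drop = FALSE]
    Vk <- vecs[keep, , drop = FALSE]
    M <- crossprod(Nk)
    if (abs(det(M)) < .Machine$double.eps)
      stop("infer_lattice: indexed neighbour vectors are degenerate")
    B <- t(solve(M, crossprod(Nk, Vk)))
    n_used <- sum(keep)
    rms <- sqrt(mean(rowSums((Vk - Nk %*% t(B))^2)))
  }
  list(basis = B, n_used = n_used, residual = rms)
}

# Standard deviations of the displacement vectors indexed to each final
# basis vector: length scatter per axis, angle scatter per axis pair.
basis_uncertainties <- function(basis, vecs, max_residual) {
  N <- round(t(solve(basis, t(vecs))))
  res2 <- rowSums((vecs - N %*% t(basis))^2)
  ok <- res2 <= max_residual^2
  members <- lapply(1:3, function(j) {
    e <- c(0, 0, 0); e[j] <- 1
    plus <- ok & apply(N, 1L, function(r) all(r == e))
    minus <- ok & apply(N, 1L, function(r) all(r == -e))
    rbind(vecs[plus, , drop = FALSE], -vecs[minus, , drop = FALSE])
  })
  len_sd <- vapply(members, function(m) {
    if (nrow(m) < 2L) return(NA_real_)
    stats::sd(sqrt(rowSums(m^2)))
  }, numeric(1))
  ang_between <- function(u, v) {
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  pairs <- list(c(2, 3), c(1, 3), c(1, 2))  # alpha, beta, gamma
  ang_sd <- vapply(pairs, function(p) {
    mj <- members[[p[1]]]; mk <- members[[p[2]]]
    if (nrow(mj) < 2L || nrow(mk) < 2L) return(NA_real_)
    s1 <- apply(mj, 1L, ang_between, v = basis[, p[2]])
    s2 <- apply(mk, 1L, ang_between, u = basis[, p[1]])
    stats::sd(c(s1, s2))
  }, numeric(1))
  list(uncertainty = list(lengths = len_sd, angles = ang_sd),
       members = members)
}

#' Canonical cell setting of a lattice basis
#'
#' Deterministically selects, among the bases generating the same lattice,
#' the package's presentation cell. The basis is first Buerger-reduced
#' (iterated shortening by integer combinations); candidate settings are
#' then enumerated over small unimodular transforms, restricted where
#' possible to all-acute inter-axial angles, and scored by metric symmetry:
#' the number of near-equal edge-length pairs plus near-equal angle pairs.
#' The highest-scoring setting wins (ties: smallest perimeter, then
#' lexicographic); edges are presented in descending length order. For a
#' generic triclinic lattice this degenerates to the reduced all-acute cell;
#' for lattices with hidden metric symmetry — such as the Dps-DNA crystal,
#' whose conventional setting a = b = 83.3, c = 54.2 Angstrom, all angles
#' 60.5 degrees is *not* the reduced cell — it selects the symmetric
#' setting, as crystallographic convention prefers.
#'
#' @param basis 3x3 matrix, columns are lattice vectors (Angstrom).
#' @param length_tol Relative tolerance for treating two edge lengths as
#'   equal (default 0.03).
#' @param angle_tol Absolute tolerance in degrees for treating two angles
#'   as equal (default 3).
#' @return List with `basis` (3x3, columns ordered by descending length)
#'   and `transform` (integer matrix mapping input to output basis).
#' @export
canonical_cell_setting <- function(basis, length_tol = 0.03, angle_tol = 3) {
  stopifnot(is.matrix(basis), all(dim(basis) == c(3L, 3L)))
  if (abs(det(basis)) < .Machine$double.eps^0.5)
    stop("canonical_cell_setting: basis is singular")
  red <- buerger_reduce(basis)
  B <- red$basis
  maxlen <- max(sqrt(colSums(B^2)))

  # candidate lattice vectors: small integer combinations of the reduced
  # basis, one per antipodal pair, not much longer than the reduced edges
  combos <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  combos <- combos[rowSums(combos != 0) > 0L, , drop = FALSE]
  combos <- combos[apply(combos, 1L, function(r) { nz <- r[r != 0]; nz[1] > 0 }), ,
                   drop = FALSE]
  W <- combos %*% t(B)            # rows are candidate vectors
  lens <- sqrt(rowSums(W^2))
  keep <- lens <= 1.8 * maxlen + 1e-9
  combos <- combos[keep, , drop = FALSE]
  W <- W[keep, , drop = FALSE]
  lens <- lens[keep]
  ord <- order(lens)
  if (length(ord) > 40L) ord <- ord[1:40]   # bound the triple search
  combos <- combos[ord, , drop = FALSE]
  W <- W[ord, , drop = FALSE]
  lens <- lens[ord]
  nc <- nrow(W)

  best <- NULL
  consider <- function(cand) {
    if (is.null(best)) { best <<- cand; return(invisible()) }
    if (cand$acute != best$acute) {
      if (cand$acute) best <<- cand
      return(invisible())
    }
    if (cand$score != best$score) {
      if (cand$score > best$score) best <<- cand
      return(invisible())
    }
    if (abs(cand$perim - best$perim) > 1e-9 * best$perim) {
      if (cand$perim < best$perim) best <<- cand
      return(invisible())
    }
    if (lex_less(cand$key, best$key)) best <<- cand
    invisible()
  }

  for (i in seq_len(nc - 2L)) for (j in (i + 1L):(nc - 1L)) for (k in (j + 1L):nc) {
    ci <- combos[i, ]; cj <- combos[j, ]; ck <- combos[k, ]
    dM <- ci[1] * (cj[2] * ck[3] - cj[3] * ck[2]) -
          ci[2] * (cj[1] * ck[3] - cj[3] * ck[1]) +
          ci[3] * (cj[1] * ck[2] - cj[2] * ck[1])
    if (abs(dM) != 1) next
    M <- rbind(ci, cj, ck)
    Bt <- t(rbind(W[i, ], W[j, ], W[k, ]))  # columns are the triple
    cand <- score_setting(Bt, length_tol, angle_tol)
    if (is.null(cand)) next
    cand$transform <- M
    consider(cand)
  }
  if (is.null(best))
    stop("canonical_cell_setting: no unimodular setting found (degenerate basis)")
  list(basis = best$basis,
       transform = best$transform %*% red$transform)
}

lex_less <- function(a, b) {
  d <- round(a - b, 6)
  nz <- which(d != 0)
  length(nz) > 0L && d[nz[1]] < 0
}

# Sign-adjust a candidate triple toward all-acute angles, order columns by
# descending length, and score its metric symmetry.
score_setting <- function(B, length_tol, angle_tol) {
  g <- crossprod(B)
  lens <- sqrt(diag(g))
  best_flip <- NULL
  for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    cosv <- c(s2 * g[1, 2] / (lens[1] * lens[2]),
              s3 * g[1, 3] / (lens[1] * lens[3]),
              s2 * s3 * g[2, 3] / (lens[2] * lens[3]))
    n_acute <- sum(cosv >= -1e-12)
    if (is.null(best_flip) || n_acute > best_flip$n_acute)
      best_flip <- list(s = c(1, s2, s3), n_acute = n_acute, cosv = cosv)
  }
  s <- best_flip$s
  Bs <- B %*% diag(s)
  acute <- best_flip$n_acute == 3L
  # order by descending length; angles follow the edge permutation
  ordc <- order(-lens)
  Bs <- Bs[, ordc, drop = FALSE]
  g <- crossprod(Bs)
  lens <- sqrt(diag(g))
  angs <- c(acos(max(-1, min(1, g[2, 3] / (lens[2] * lens[3])))),
            acos(max(-1, min(1, g[1, 3] / (lens[1] * lens[3])))),
            acos(max(-1, min(1, g[1, 2] / (lens[1] * lens[2]))))) * 180 / pi
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  score <- 0L
  for (p in pairs) {
    if (abs(lens[p[1]] - lens[p[2]]) / mean(lens[p]) < length_tol)
      score <- score + 1L
    if (abs(angs[p[1]] - angs[p[2]]) < angle_tol)
      score <- score + 1L
  }
  list(basis = Bs, acute = acute, score = score, perim = sum(lens),
       key = c(lens, angs))
}

# Iterative Buerger-style reduction: shorten basis vectors by integer
# combinations of the others until no single substitution helps.
buerger_reduce <- function(basis, max_iter = 60) {
  B <- basis
  Tm <- diag(3)
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (i in 1:3) {
      others <- setdiff(1:3, i)
      li <- sum(B[, i]^2)
      for (s1 in -1:1) for (s2 in -1:1) {
        if (s1 == 0L && s2 == 0L) next
        cand <- B[, i] + s1 * B[, others[1]] + s2 * B[, others[2]]
        if (sum(cand^2) < li - 1e-9 * li) {
          B[, i] <- cand
          Tm[i, ] <- Tm[i, ] + s1 * Tm[others[1], ] + s2 * Tm[others[2], ]
          li <- sum(cand^2)
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(basis = B, transform = Tm)
}

#' Canonical form of a unit cell
#'
#' Applies the package's cell-setting convention (see
#' [canonical_cell_setting()]) to a cell's own lattice: the result describes
#' the same lattice in the presentation setting that [infer_lattice()]
#' reports. Useful for comparing ground-truth and recovered constants.
#'
#' @param cell A [unit_cell()].
#' @inheritParams canonical_cell_setting
#' @return A [unit_cell()].
#' @export
canonical_cell <- function(cell, length_tol = 0.03, angle_tol = 3) {
  cell_from_basis(canonical_cell_setting(cell_basis(cell), length_tol,
                                         angle_tol)$basis)
}

#' Extract periodic spacings from a projection image by FFT
#'
#' Computes the 2D power spectrum of a (mean-subtracted, Hann-windowed)
#' projection image, finds dominant non-DC peaks, merges Hermitian-symmetric
#' pairs, refines peak positions by parabolic interpolation, and converts
#' them to real-space spacings d = 1/|f| with in-plane orientations.
#'
#' @param image Numeric matrix (at least 17 x 17), e.g. from
#'   [generate_projection_image()].
#' @param pixel_size Pixel edge in angstroms.
#' @param min_power_frac A peak must carry at least this fraction of the
#'   total non-DC spectral power (default 0.02).
#' @param max_peaks Maximum number of spacings returned.
#' @return List with `spacings` (data frame: `spacing` in Angstrom,
#'   `orientation_deg`, `power_fraction`, sorted by decreasing power) and
#'   `no_signal` (TRUE when no peak clears the floor, e.g. a flat image).
#' @export
spacing_from_projection <- function(image, pixel_size, min_power_frac = 0.02,
                                    max_peaks = 6) {
  image <- as.matrix(image)
  if (nrow(image) < 17L || ncol(image) < 17L)
    stop("spacing_from_projection: image must be larger than 16 x 16")
  if (pixel_size <= 0) stop("spacing_from_projection: pixel_size must be > 0")
  nu <- nrow(image); nv <- ncol(image)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  w <- outer(hann(nu), hann(nv))
  a <- (image - mean(image)) * w
  P <- Mod(stats::fft(a))^2
  # frequency (cycles per Angstrom) per axis, fftshift-free indexing
  fu <- c(0:(nu %/% 2), -((nu - nu %/% 2 - 1):1)) / (nu * pixel_size)
  fv <- c(0:(nv %/% 2), -((nv - nv %/% 2 - 1):1)) / (nv * pixel_size)
  ku <- c(0:(nu %/% 2), -((nu - nu %/% 2 - 1):1))
  kv <- c(0:(nv %/% 2), -((nv - nv %/% 2 - 1):1))
  near_dc <- outer(abs(ku) <= 1L, abs(kv) <= 1L)
  total <- sum(P[!near_dc])
  empty <- data.frame(spacing = numeric(0), orientation_deg = numeric(0),
                      power_fraction = numeric(0))
  if (total <= 0) return(list(spacings = empty, no_signal = TRUE))
  # keep one of each Hermitian pair: fu > 0, or fu == 0 & fv > 0
  half <- outer(ku > 0L, rep(TRUE, nv)) | outer(ku == 0L, kv > 0L)
  cand <- which(half & !near_dc, arr.ind = TRUE)
  pw <- P[cand]
  ord <- order(-pw)
  cand <- cand[ord, , drop = FALSE]
  pw <- pw[ord]
  out <- empty
  taken <- matrix(FALSE, nu, nv)
  for (t in seq_along(pw)) {
    iu <- cand[t, 1]; iv <- cand[t, 2]
    # local-neighbourhood power (3x3, both Hermitian mates) as the peak mass
    du <- ((iu - 2):(iu)) %% nu + 1L
    dv <- ((iv - 2):(iv)) %% nv + 1L
    if (any(taken[du, dv])) next
    mass <- 2 * sum(P[du, dv])
    if (mass / total < min_power_frac) break
    taken[du, dv] <- TRUE
    # parabolic sub-bin refinement along each axis
    ref1 <- function(pm, p0, pp) {
      den <- pm - 2 * p0 + pp
      if (abs(den) < .Machine$double.eps) 0 else max(-0.5, min(0.5, 0.5 * (pm - pp) / den))
    }
    um <- (iu - 2) %% nu + 1L; up <- iu %% nu + 1L
    vm <- (iv - 2) %% nv + 1L; vp <- iv %% nv + 1L
    dfu <- ref1(P[um, iv], P[iu, iv], P[up, iv]) / (nu * pixel_size)
    dfv <- ref1(P[iu, vm], P[iu, iv], P[iu, vp]) / (nv * pixel_size)
    f <- c(fu[iu] + dfu, fv[iv] + dfv)
    fmag <- sqrt(sum(f^2))
    if (fmag <= 0) next
    out <- rbind(out, data.frame(spacing = 1 / fmag,
                                 orientation_deg = atan2(f[2], f[1]) * 180 / pi,
                                 power_fraction = mass / total))
    if (nrow(out) >= max_peaks) break
  }
  list(spacings = out, no_signal = nrow(out) == 0L)
}
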