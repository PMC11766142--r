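# Shared fixtures and independent oracles used across the suite.

# The triclinic cell fitted to the in vitro Dps-DNA crystal.
dps_cell <- function() unit_cell(83.3, 83.3, 54.2, 60.5, 60.5, 60.5)

# The four interplanar distances read off the experimental SAXS curve (A).
saxs_d_list <- c(69.6, 54.5, 45.0, 34.4)

# Independent explicit lattice-vector construction (a along x, b in the
# xy-plane, c by the standard crystallographic construction). Kept separate
# from the package's cell_basis() so the two routes can be cross-checked.
oracle_basis <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cbind(c(a, 0, 0),
        c(b * cg, b * sg, 0),
        c(cx, cy, sqrt(c^2 - cx^2 - cy^2)))
}

oracle_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# d-spacing via reciprocal vectors built from cross products: an
# independent route compared with the package's inverse-metric-tensor path.
oracle_d_spacing <- function(cell, hkl) {
  B <- oracle_basis(cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)
  V <- sum(B[, 1] * oracle_cross(B[, 2], B[, 3]))
  recip <- cbind(oracle_cross(B[, 2], B[, 3]),
                 oracle_cross(B[, 3], B[, 1]),
                 oracle_cross(B[, 1], B[, 2])) / V
  if (is.null(dim(hkl))) hkl <- matrix(hkl, nrow = 1)
  apply(hkl, 1L, function(h) 1 / sqrt(sum((recip %*% h)^2)))
}

# Brute-force reflection enumeration over a generous index cube.
oracle_reflections <- function(cell, d_min, bound = 6L) {
  grid <- as.matrix(expand.grid(h = -bound:bound, k = -bound:bound,
                                l = -bound:bound))
  grid <- grid[rowSums(grid != 0) > 0L, , drop = FALSE]
  keep <- apply(grid, 1L, function(r) { nz <- r[r != 0]; nz[1] > 0 })
  grid <- grid[keep, , drop = FALSE]
  d <- oracle_d_spacing(cell, grid)
  grid[d >= d_min, , drop = FALSE]
}

# Brute-force structure factor by direct complex-exponential summation.
oracle_structure_factor <- function(scatterers, cell, hkl) {
  B <- oracle_basis(cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)
  frac <- t(solve(B, t(scatterers$sites)))
  d <- oracle_d_spacing(cell, hkl)
  f <- 0 + 0i
  for (j in seq_len(nrow(frac))) {
    damp <- exp(-2 * pi^2 * scatterers$width[j]^2 / d^2)
    f <- f + scatterers$weight[j] * damp *
      exp(2i * pi * sum(frac[j, ] * hkl))
  }
  Mod(f)^2
}

# A random valid triclinic cell (realizability enforced by rejection).
random_cell <- function() {
  repeat {
    a <- runif(1, 8, 30); b <- runif(1, 8, 30); c <- runif(1, 8, 30)
    al <- runif(1, 50, 130); be <- runif(1, 50, 130); ga <- runif(1, 50, 130)
    ca <- cos(al * pi / 180); cb <- cos(be * pi / 180); cg <- cos(ga * pi / 180)
    if (1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg > 0.05)
      return(unit_cell(a, b, c, al, be, ga))
  }
}
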