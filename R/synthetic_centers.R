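# Synthetic generators for oligomer-centre lattices and point-scatterer
# crystal models. These emulate the experimental objects the pipeline
# consumes (tomography-derived trimer centres; the trimer+DNA crystal model)
# with known ground truth, so every downstream stage is testable.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Set of oligomer-centre coordinates
#'
#' Container for a 3D point cloud of oligomer (trimer) centres, optionally
#' carrying the ground truth it was generated from.
#'
#' @param points n x 3 numeric matrix of coordinates in angstroms.
#' @param label Free-text provenance.
#' @param ground_truth Optional list (cell, jitter_sigma, vacancy_rate,
#'   extents) recorded by [generate_lattice_centers()].
#' @return Object of class `center_set`.
#' @export
center_set <- function(points, label = "", ground_truth = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("center_set: points must have three columns")
  if (nrow(points) < 1L) stop("center_set: at least one point required")
  if (any(!is.finite(points))) stop("center_set: coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, label = label, ground_truth = ground_truth),
            class = "center_set")
}

#' @export
print.center_set <- function(x, ...) {
  cat(sprintf("center_set: %d points%s\n", nrow(x$points),
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  if (!is.null(x$ground_truth))
    cat("  ground truth:", format(x$ground_truth$cell), "\n")
  invisible(x)
}

#' Generate a jittered finite lattice of oligomer centres
#'
#' Places points at every node \eqn{i\,a + j\,b + k\,c} of a finite block of
#' the lattice, removes each independently with probability `vacancy_rate`,
#' displaces each survivor by isotropic Gaussian noise of standard deviation
#' `jitter_sigma` per axis, and (optionally) subsamples to at most `n_max`
#' points. This is the synthetic stand-in for trimer centres read off a
#' tomographic density map.
#'
#' @param cell A [unit_cell()] (ground truth).
#' @param extents Integer triple: number of cells along a, b, c.
#' @param jitter_sigma Positional noise per axis, angstroms (default 1.5).
#' @param vacancy_rate Probability a node is unoccupied, in `[0, 1)`.
#' @param n_max Optional cap: if more nodes survive, a uniform random
#'   subsample of exactly `n_max` is kept (emulates a fixed number of
#'   placed oligomers, e.g. 150).
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @return A [center_set()] with `ground_truth` recorded.
#' @export
generate_lattice_centers <- function(cell, extents, jitter_sigma = 1.5,
                                     vacancy_rate = 0, n_max = NULL,
                                     seed = NULL) {
  assert_unit_cell(cell)
  extents <- as.integer(extents)
  if (length(extents) != 3L || any(extents < 1L))
    stop("generate_lattice_centers: extents must be three integers >= 1")
  if (jitter_sigma < 0) stop("generate_lattice_centers: jitter_sigma must be >= 0")
  if (vacancy_rate < 0 || vacancy_rate >= 1)
    stop("generate_lattice_centers: vacancy_rate must be in [0, 1)")
  basis <- cell_basis(cell)
  idx <- as.matrix(expand.grid(i = 0:(extents[1] - 1L),
                               j = 0:(extents[2] - 1L),
                               k = 0:(extents[3] - 1L)))
  pts <- idx %*% t(basis)
  with_local_seed(seed, {
    keep <- stats::runif(nrow(pts)) >= vacancy_rate
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) == 0L)
      stop("generate_lattice_centers: all nodes vacant; re-seed or lower vacancy_rate")
    if (!is.null(n_max) && nrow(pts) > n_max)
      pts <- pts[sort(sample.int(nrow(pts), n_max)), , drop = FALSE]
    if (jitter_sigma > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), sd = jitter_sigma),
                          nrow = nrow(pts))
    center_set(pts,
               label = sprintf("synthetic lattice %dx%dx%d",
                               extents[1], extents[2], extents[3]),
               ground_truth = list(cell = cell, jitter_sigma = jitter_sigma,
                                   vacancy_rate = vacancy_rate,
                                   extents = extents))
  })
}

#' Set of point scatterers
#'
#' @param sites n x 3 matrix of coordinates (Angstrom).
#' @param weight Scattering weight per site (recycled); must be >= 0.
#' @param width Gaussian width (sigma, Angstrom) per site (recycled); a
#'   point scatterer has width 0.
#' @param label Free-text provenance.
#' @return Object of class `scatterer_set`.
#' @export
scatterer_set <- function(sites, weight = 1, width = 0, label = "") {
  sites <- as.matrix(sites)
  if (ncol(sites) != 3L) stop("scatterer_set: sites must have three columns")
  if (nrow(sites) < 1L) stop("scatterer_set: at least one site required")
  weight <- rep_len(as.numeric(weight), nrow(sites))
  width <- rep_len(as.numeric(width), nrow(sites))
  if (any(weight < 0)) stop("scatterer_set: weights must be >= 0")
  if (any(width < 0)) stop("scatterer_set: widths must be >= 0")
  colnames(sites) <- c("x", "y", "z")
  structure(list(sites = sites, weight = weight, width = width, label = label),
            class = "scatterer_set")
}

#' @export
print.scatterer_set <- function(x, ...) {
  cat(sprintf("scatterer_set: %d sites, total weight %.4g%s\n",
              nrow(x$sites), sum(x$weight),
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}

#' Default pseudo-atomic trimer motif
#'
#' Three beads at 120 degrees on a circle in the ab-plane: a coarse,
#' torus-like stand-in for the three monomers of a Dps trimer (particle
#' roughly 70 Angstrom across and 44 high). Bead width approximates the
#' monomer envelope.
#'
#' @param radius Circle radius in angstroms (default 20).
#' @param weight Weight per bead (default 1).
#' @param width Gaussian width per bead in angstroms (default 10).
#' @return A [scatterer_set()] with three sites centred on the origin.
#' @export
trimer_motif <- function(radius = 20, weight = 1, width = 10) {
  ang <- c(0, 2, 4) * pi / 3
  scatterer_set(cbind(radius * cos(ang), radius * sin(ang), 0),
                weight = weight, width = width, label = "trimer motif")
}

#' Build a point-scatterer crystal of trimers with optional DNA rods
#'
#' Replicates `motif` on every node of a finite lattice block. If
#' `dna_rod = TRUE`, additional beads representing the DNA duplex are laid
#' along the c-axis direction through the inter-trimer channel at fractional
#' offset `rod_offset` in the ab-plane, spaced `rod_spacing` apart (the
#' default spacing is the B-DNA base rise, 3.4 Angstrom).
#'
#' @param cell A [unit_cell()].
#' @param extents Integer triple: crystal block size in unit cells.
#' @param motif A [scatterer_set()]; replicated at every node.
#' @param dna_rod Logical: add DNA beads in the through channels?
#' @param rod_spacing Bead spacing along the rod, angstroms (> 0).
#' @param rod_offset Fractional (a, b) offset of the channel (default
#'   c(0.5, 0.5)).
#' @param rod_weight,rod_width Weight and Gaussian width of DNA beads.
#' @return A [scatterer_set()] for the whole crystal block.
#' @export
generate_crystal_scatterers <- function(cell, extents, motif = trimer_motif(),
                                        dna_rod = TRUE, rod_spacing = 3.4,
                                        rod_offset = c(0.5, 0.5),
                                        rod_weight = 0.05, rod_width = 8) {
  assert_unit_cell(cell)
  if (!inherits(motif, "scatterer_set")) stop("motif must be a scatterer_set")
  extents <- as.integer(extents)
  if (length(extents) != 3L || any(extents < 1L))
    stop("generate_crystal_scatterers: extents must be three integers >= 1")
  if (dna_rod && rod_spacing <= 0)
    stop("generate_crystal_scatterers: rod_spacing must be > 0 when dna_rod is on")
  basis <- cell_basis(cell)
  nodes <- as.matrix(expand.grid(i = 0:(extents[1] - 1L),
                                 j = 0:(extents[2] - 1L),
                                 k = 0:(extents[3] - 1L))) %*% t(basis)
  nn <- nrow(nodes)
  nm <- nrow(motif$sites)
  sites <- nodes[rep(seq_len(nn), each = nm), , drop = FALSE] +
    motif$sites[rep(seq_len(nm), nn), , drop = FALSE]
  weight <- rep(motif$weight, nn)
  width <- rep(motif$width, nn)
  if (dna_rod) {
    cvec <- basis[, 3]
    clen <- sqrt(sum(cvec^2))
    chat <- cvec / clen
    rod_len <- extents[3] * clen
    tpos <- seq(0, rod_len, by = rod_spacing)
    ab <- as.matrix(expand.grid(i = 0:(extents[1] - 1L),
                                j = 0:(extents[2] - 1L)))
    anchors <- sweep(ab, 2, rod_offset, "+") %*% t(basis[, 1:2])
    rod <- anchors[rep(seq_len(nrow(anchors)), each = length(tpos)), , drop = FALSE] +
      outer(rep(tpos, nrow(anchors)), chat)
    sites <- rbind(sites, rod)
    weight <- c(weight, rep(rod_weight, nrow(rod)))
    width <- c(width, rep(rod_width, nrow(rod)))
  }
  scatterer_set(sites, weight, width,
                label = sprintf("trimer crystal %dx%dx%d%s", extents[1],
                                extents[2], extents[3],
                                if (dna_rod) " + DNA rods" else ""))
}
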