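# Scalar analyses supporting the trimer assignment: thermodynamic-
# integration bookkeeping of subunit binding free energies, the shifted
# Lennard-Jones 12-6 potential, and rigid-volume monomer-capacity bounds.

#' Thermodynamic-integration record for one trimer type
#'
#' Holds the two alchemical Gibbs energies from which a subunit binding
#' energy is formed: the solvation energy (ghost state to fully solvated
#' monomer) and the bound-state energy (ghost state to monomer bound in the
#' trimer), each with its standard error.
#'
#' @param dG_solvation Solvation Gibbs energy, kJ/mol.
#' @param dG_bound Bound-state Gibbs energy, kJ/mol.
#' @param err_solvation,err_bound Standard errors, kJ/mol (>= 0).
#' @param label Trimer type, e.g. `"Dps-type pore"`.
#' @return Object of class `ti_record`.
#' @export
ti_record <- function(dG_solvation, dG_bound, err_solvation = 0,
                      err_bound = 0, label = "") {
  for (v in list(dG_solvation, dG_bound, err_solvation, err_bound))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("ti_record: all energies and errors must be single finite numbers")
  if (err_solvation < 0 || err_bound < 0)
    stop("ti_record: standard errors must be >= 0")
  structure(list(dG_solvation = dG_solvation, dG_bound = dG_bound,
                 err_solvation = err_solvation, err_bound = err_bound,
                 label = label),
            class = "ti_record")
}

#' Subunit binding free energy from a TI record
#'
#' \eqn{\Delta\Delta G = \Delta G_{bound} - \Delta G_{solvation}}, with the
#' error propagated in quadrature
#' \eqn{\sqrt{err_{bound}^2 + err_{solv}^2}} (the two TI runs are
#' independent). The full-precision value is reported alongside its
#' integer-rounded form.
#'
#' @param record A [ti_record()].
#' @return List with `ddG` (kJ/mol), `err` (kJ/mol), `ddG_rounded`
#'   (nearest integer) and `label`.
#' @examples
#' # Dps-type pore trimer: Delta-G1 (solvation) and Delta-G2 (bound)
#' binding_delta_g(ti_record(-1787.7, -1903.16, 27.7, 32.05, "Dps-type"))
#' @export
binding_delta_g <- function(record) {
  if (!inherits(record, "ti_record")) stop("binding_delta_g: expected a ti_record")
  ddG <- record$dG_bound - record$dG_solvation
  err <- sqrt(record$err_bound^2 + record$err_solvation^2)
  list(ddG = ddG, err = err, ddG_rounded = round(ddG), label = record$label)
}

#' Lennard-Jones 12-6 potential, optionally shifted
#'
#' \eqn{U(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}; with
#' `shift = TRUE` the potential is shifted by its value at `r_cutoff` so
#' that \eqn{U(r_{cutoff}) = 0}, as used for non-bonded interactions in
#' coarse-grained simulations with a 1.2 nm cutoff.
#'
#' @param r Distance(s), nm (> 0).
#' @param epsilon Well depth, kJ/mol (> 0).
#' @param sigma Zero-crossing distance, nm (> 0); e.g. 0.47 for ordinary
#'   water beads, 0.57 for the ordinary-antifreeze cross term.
#' @param shift Apply the cutoff shift? Default `FALSE`.
#' @param r_cutoff Cutoff distance, nm (default 1.2).
#' @return Energy value(s), kJ/mol.
#' @export
lj_potential <- function(r, epsilon, sigma, shift = FALSE, r_cutoff = 1.2) {
  if (any(r <= 0)) stop("lj_potential: r must be > 0")
  if (epsilon <= 0 || sigma <= 0)
    stop("lj_potential: epsilon and sigma must be > 0")
  u <- function(x) { sr6 <- (sigma / x)^6; 4 * epsilon * (sr6^2 - sr6) }
  if (shift) u(r) - u(r_cutoff) else u(r)
}

#' Monomer capacity of an oligomeric particle by rigid volumes
#'
#' How many monomers (as rigid bounding boxes) fit into the particle
#' volume: `floor(V_particle / V_monomer)`. Three particle-volume modes:
#' `"box"` treats the toroid as its d x d x h bounding box, `"cylinder"` as
#' a solid cylinder \eqn{\pi (d/2)^2 h}, `"cylinder_minus_cavity"`
#' additionally subtracts a coaxial cavity cylinder. This is a volume
#' bound, not a packing algorithm: for the 70 x 70 x 44 Angstrom Dps toroid
#' and a 58 x 25 x 35 Angstrom monomer the box mode gives 4 and the
#' cylinder mode 3 (the trimer).
#'
#' @param particle_diameter,particle_height Particle dimensions, angstroms.
#' @param monomer Length-3 vector of monomer bounding-box edges, angstroms.
#' @param mode `"box"`, `"cylinder"` or `"cylinder_minus_cavity"`.
#' @param cavity_diameter Cavity diameter, angstroms (required for the
#'   cavity mode; must be smaller than the particle diameter).
#' @return Integer monomer count (0 when the monomer exceeds the particle).
#' @examples
#' monomer_capacity(70, 44, c(58, 25, 35), mode = "box")       # 4
#' monomer_capacity(70, 44, c(58, 25, 35), mode = "cylinder")  # 3
#' @export
monomer_capacity <- function(particle_diameter, particle_height, monomer,
                             mode = c("box", "cylinder",
                                      "cylinder_minus_cavity"),
                             cavity_diameter = NULL) {
  mode <- match.arg(mode)
  if (particle_diameter <= 0 || particle_height <= 0)
    stop("monomer_capacity: particle dimensions must be > 0")
  if (length(monomer) != 3L || any(monomer <= 0))
    stop("monomer_capacity: monomer must be three positive edges")
  v_particle <- switch(mode,
    box = particle_diameter^2 * particle_height,
    cylinder = pi * (particle_diameter / 2)^2 * particle_height,
    cylinder_minus_cavity = {
      if (is.null(cavity_diameter) || cavity_diameter <= 0 ||
          cavity_diameter >= particle_diameter)
        stop("monomer_capacity: cavity_diameter must be in (0, particle_diameter)")
      pi * ((particle_diameter / 2)^2 - (cavity_diameter / 2)^2) *
        particle_height
    })
  v_monomer <- prod(monomer)
  max(0L, as.integer(floor(v_particle / v_monomer)))
}
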