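---
title: "Methods: lattice inference and powder-pattern analysis for Dps-DNA crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice inference and powder-pattern analysis for Dps-DNA crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpslattice)
```

## Scientific setting

Dps, the major DNA-binding protein of starved bacteria, packages the
chromosome into intracellular protein-DNA crystals. The repeat distances
observed in such crystals are smaller than the ~90 Å dodecamer the protein
forms in solution, which points to a smaller crystal-forming unit: a
torus-shaped trimer of roughly 70 Å diameter and 44 Å height. Three
independent computational strands support that assignment, and this
package implements all of them on a common set of containers
(`unit_cell`, `center_set`, `scatterer_set`, `curve1d`, `detector_image`):

1. the triclinic lattice constants recoverable from trimer-centre
   coordinates (a = b = 83.3 ± 3.2 Å, c = 54.2 ± 2.7 Å, all inter-axial
   angles ≈ 60.5 ± 4°);
2. the agreement between the powder pattern of the model trimer/DNA
   crystal and the four experimental SAXS interplanar distances
   (69.6, 54.5, 45.0, 34.4 Å at λ = 1.542 Å);
3. scalar evidence: trimer binding free energies assembled from
   thermodynamic-integration runs, and the volume argument that at most
   four monomers fit the particle's bounding box but only three its
   cylindrical volume.

## Units

Internal length unit is the angstrom everywhere, angles are degrees at
every interface (radians internally), detector distances and pixel pitches
are millimetres, and energies kJ/mol. Published particle dimensions
written with nanometre units but angstrom-scale magnitudes
(e.g. "70 × 70 × 44" for the toroid, "58 × 25 × 35" for the monomer) are
interpreted as angstroms throughout; a 70 nm protein torus would exceed
the cell's crystal spacing by an order of magnitude.

## Unit-cell mathematics

`metric_tensor()` builds the Gram matrix analytically from the six cell
constants; `cell_basis()` fixes the Cartesian orientation convention
(a along x, b in the xy-plane, c by the standard crystallographic
construction) that the generators and structure factors share, so that
fractionalisation is reproducible. `d_spacing()` uses
$d = 1/\sqrt{\mathbf{h}^T G^{-1} \mathbf{h}}$; the test suite cross-checks
it against an independent construction of reciprocal vectors from cross
products. `enumerate_reflections()` bounds the index search per axis by
the Cauchy–Schwarz inequality $|h| \le a/d_{\min}$ (plus one index of
margin) and stores one reflection per Friedel pair, canonicalised so the
first nonzero index is positive. The q convention is
$q = 4\pi\sin\theta/\lambda$, $d = 2\pi/q$, consistent with the
experimental d list.

## The synthetic-data generators

`generate_lattice_centers()` emulates trimer centres read off a
tomographic density map: lattice nodes over a finite block, independent
vacancies, isotropic Gaussian jitter, and an optional uniform subsample to
a fixed count. The study conditions used throughout the tests are the
experimental ones: 150 centres (a 6 × 6 × 5 block thinned by 5% vacancies
and subsampled), jitter σ = 1.5 Å — chosen so that the recovery targets
sit well inside the published ± values while remaining a realistic
placement error for fitting a trimer into ~20 Å resolution density.

`trimer_motif()` is a deliberately coarse stand-in for the all-atom
trimer: three beads of unit weight at 120° on a 20 Å circle, Gaussian
width 10 Å (approximately the monomer envelope). `generate_crystal_scatterers()`
replicates it on every node and, when `dna_rod = TRUE`, lays DNA beads
along the c-direction through the inter-trimer channel at the B-DNA rise
(3.4 Å), at fractional ab-offset (1/2, 1/2); the experimental location of
the DNA in the through channel is known only qualitatively, so the offset
is configurable. Bead widths only damp intensities
($f_j = e^{-2\pi^2\sigma_j^2/d^2}$); they never move peak positions, which
are the quantity compared with experiment.

`synthesize_powder_curve()` models an experimental powder curve as a
power-law-plus-constant background (the "amorphous" component) plus
Gaussian Bragg peaks, with optional Poisson counting noise that preserves
the expectation. `render_detector_image()` maps a 1D curve onto a flat
detector with $2\theta = \arctan(r/D)$; the default geometry is the
experimental one (λ = 1.542 Å, D = 2 m) with a 0.2 mm pixel, which puts
the 69.6 Å ring comfortably inside a 512² frame; the end-to-end pipeline
uses 1024² so that all four experimental rings fall on the detector.

What the generators do *not* emulate: tomographic missing-wedge
anisotropy, TEM contrast transfer, detector flat-field or dark current,
absorption, preferred orientation, or instrument profile convolution.
Passing closure tests therefore demonstrates the correctness of the
analysis chain, not the fidelity of any microscope or beamline model.

## Lattice inference

The pair distance distribution is a Gaussian KDE over all pairwise
distances (default bandwidth 1.5 Å); the pair angle distribution pools,
per centre, the angles between displacement vectors to all neighbours
within a cutoff (default bandwidth 3°). The "pair angle" concept is
defined here explicitly as *angles between pairs of neighbour displacement
vectors at a common centre* — this is the interpretation that reproduces
the experimental 60.5°/121.1° modes. The two printed modes are not forced
to be supplementary, and indeed the perfect lattice's obtuse mode sits
near 119.5°–121° depending on which neighbour shells the cutoff admits.

`infer_lattice()` does not work from the scalar distributions; it
reconstructs the basis directly:

1. displacement vectors between all centre pairs within the cutoff
   (default 100 Å, which must exceed the longest expected edge);
2. greedy antipodal-aware clustering in order of increasing length
   (tolerance 8 Å by default — large against the ~2 Å vector noise at
   jitter 1.5 Å, small against the ≥ 15 Å separation of distinct lattice
   vectors in this crystal);
3. basis candidate: the three shortest cluster means with pairwise
   normalised cross products and a normalised triple product above 0.15;
4. least-squares refinement against every displacement vector indexed to
   its nearest integer combination, iterated with outlier rejection at
   the cluster tolerance;
5. canonical cell setting (below).

Uncertainties are standard deviations over the displacement vectors
indexed to each basis vector — cluster scatter, mirroring the ± style of
the experimental report rather than fit covariances, which would
overstate confidence by assuming independent Gaussian residuals.

### The cell-setting convention

A lattice has infinitely many generating bases, so "the" cell constants
are a convention. The Buerger-reduced (shortest-vector) basis of the
Dps-DNA lattice is **not** the published setting: with
a = b = 83.3, c = 54.2 Å and all angles 60.5°, the combinations a − c and
b − c are only 73.7 Å long, so the reduced cell is
(73.7, 73.7, 54.2 Å; 69.4°, 79.7°, 79.7°). The published setting is the
one that displays the lattice's metric symmetry (a = b, α = β = γ), which
is what crystallographic convention prefers whenever a conventional cell
exhibits more symmetry than the reduced one.

`canonical_cell_setting()` therefore Buerger-reduces the fitted basis,
enumerates candidate settings over small unimodular transforms (integer
coefficients up to ±2, lengths up to 1.8× the longest reduced edge),
restricts to all-acute settings where any exist, and scores each setting
by its metric symmetry: the number of near-equal edge-length pairs
(relative tolerance 3%) plus near-equal angle pairs (3°). The highest
score wins; ties fall to the smallest perimeter and then to a lexicographic
key, so the choice is deterministic and invariant under rigid motions of
the input points. For a generic triclinic lattice no coincidences occur
and the convention degenerates to the reduced all-acute cell; for the
Dps-DNA lattice the symmetric setting scores 4 against the reduced cell's
2 and is selected. Edges are presented in descending length order,
matching the a = b > c presentation. The tolerances are comfortably wider
than the scatter of fitted constants under the study conditions
(standard errors of cluster means ≈ 0.2–0.5 Å) and comfortably narrower
than any spurious coincidence the lattice offers.

## Powder simulation

Structure factors are direct complex sums over one cell's worth of
scatterers with Gaussian form-factor damping. Peak profiles are Gaussian —
the experimental modelling choice — with Scherrer width
FWHM = Kλ/(L cos θ), K = 0.9 (the value for near-equiaxed crystallites;
the experimental report only ties the width to a 200 nm crystal size, so
K is exposed as a parameter), σ = FWHM / (2√(2 ln 2)). Every canonical P1
reflection carries multiplicity 2 (its Friedel mate) and no other
symmetry. The Lorentz/polarization correction is off by default: it
rescales intensities but does not move peak positions, and positions are
the acceptance surface; a toggle is provided. The default resolution
limit d ≥ 30 Å covers the four experimental peaks with margin while
keeping the reflection list at 21 entries.

## Image reduction

Azimuthal averaging bins pixels by exact $2\theta = \arctan(r/D)$ (the
small-angle approximation would be good to ~10⁻⁴ here, but the exact form
costs nothing); empty bins are marked invalid and interpolated only for
baseline continuity, never treated as zeros. The background estimator is
an iterative-clipping (SNIP-style) baseline: each interior sample is
replaced by the minimum of itself and the mean of its two neighbours
`window` bins away (defaults: window 15 bins, up to 200 passes with early
convergence stop). Consequences worth knowing: the baseline never exceeds
the curve; it is idempotent at convergence; convex smooth backgrounds are
preserved exactly; and the first/last `window` samples are never clipped,
so a peak closer than the window to the grid edge will be absorbed into
the baseline. Peak positions are refined by three-point parabolic
interpolation (ties broken toward larger d) and converted to q and d
through the Bragg relations. The peak floor is a fraction of the curve
maximum (default 2%), so a pure-noise residual yields an empty list. When
the caller knows the expected Scherrer width, a peak whose measured
log-curvature width exceeds it by more than 2% is flagged as possibly
blended; two equal Gaussians half a width apart trip this flag while a
clean single peak does not.

## Energetics and packing

`binding_delta_g()` assembles ΔΔG = ΔG_bound − ΔG_solvation from the
printed TI energies. The experimental inputs
(ΔG₁ = −1787.7 ± 27.7, ΔG₂ = −1903.16 ± 32.05, ΔG₃ = −1973.68 ± 27.08
kJ/mol) give −115.46 kJ/mol for the Dps-type pore trimer and
−185.98 kJ/mol for the ferritin-like one; the published rounded values are
−115 and −185, and the package reports full precision alongside the
integer rounding so the ≤ 1 kJ/mol discrepancy in the second figure is
visible rather than silently inherited. Errors are propagated in
quadrature — the source reports none on the differences, so this is an
extension, flagged as such. `monomer_capacity()` is deliberately a
rigid-volume floor-division bound, not a packing algorithm: the
four-versus-three argument is arithmetic, and the cylinder mode reproduces
"three" without needing an explicit cavity volume (which was never
quantified); the cavity mode exists for sensitivity analysis.

## Pipeline, seeds and problem sizes

`run_pipeline()` chains generate → infer → simulate → render → reduce →
match → energetics with a single global seed fanned out as
`seed × 1000 + stage index` (kept below 2³¹), so any stage can be rerun in
isolation; identical configuration and seed give identical outputs. The
default problem sizes — 150 centres, 21 reflections, a 1024² detector
frame, 512 radial bins — run the full chain in roughly two seconds and
keep the complete test suite under a minute, while leaving every
statistical margin (e.g. ≥ 95% of 100 replicate recoveries inside the
published uncertainty bands) intact.

## Known limitations

* The inference assumes a single crystalline domain; multi-domain point
  sets would need segmentation first (the generator can produce them, the
  fitter does not separate them).
* The cell-setting symmetry score uses fixed tolerances (3%, 3°); lattices
  whose accidental near-coincidences sit exactly at those tolerances could
  flip settings between noisy replicates. Under the study conditions this
  was never observed in 100 replicates.
* Gaussian-bead scatterer models reproduce peak positions faithfully but
  only caricature intensities; no claim is made about matching
  experimental peak *heights*.
* Microscopy-derived quantities (crystal fractions in cell populations,
  TEM repeat distances) depend on image material that cannot be simulated
  meaningfully here; the FFT periodicity extractor is validated on
  synthetic projections with known ground truth instead.
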