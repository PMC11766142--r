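# dpslattice

Lattice inference and powder-pattern analysis for Dps–DNA protein crystals.

## The problem

Under starvation stress, the bacterial DNA-binding protein Dps condenses
chromosomal DNA into intracellular crystals. The free protein is a
dodecamer of ~90 Å diameter, yet the repeat distances measured in DNA–Dps
crystals (roughly 40–83 Å) are too small to accommodate it — evidence that
the crystal-forming unit is a smaller oligomer, a torus-shaped **trimer**
(~70 Å across, ~44 Å high). Establishing that claim requires a chain of
computations that this package implements as tested, reusable R functions:

* **Triclinic (P1) unit-cell mathematics** — metric tensors
  \(G_{ij} = \mathbf{v}_i\cdot\mathbf{v}_j\), cell volumes, interplanar
  spacings \(d_{hkl} = 1/\sqrt{\mathbf{h}^T G^{-1}\mathbf{h}}\), reflection
  enumeration to a resolution limit, and conversions among d, q and 2θ
  with \(q = 4\pi\sin\theta/\lambda\), \(d = 2\pi/q\).
* **Lattice inference from oligomer centres** — pair-distance and
  pair-angle distribution functions, antipodal clustering of
  neighbour displacement vectors, least-squares basis refinement, and a
  deterministic cell-setting convention, recovering the crystal constants
  a = b = 83.3 ± 3.2 Å, c = 54.2 ± 2.7 Å, α ≅ β ≅ γ ≈ 60.5 ± 4° from
  (possibly jittered, incomplete) centre coordinates.
* **Powder-pattern simulation** — structure factors of point-scatterer
  trimer/DNA crystal models, Scherrer size broadening
  (FWHM = Kλ/(L cos θ) for a 200 nm crystallite), Gaussian peak synthesis,
  and greedy matching of model d-spacings against the four experimental
  SAXS distances 69.6, 54.5, 45.0 and 34.4 Å.
* **SAXS image reduction** — azimuthal averaging of 2D powder detector
  images, iterative-clipping (SNIP-style) background estimation, and Bragg
  peak picking with sub-bin refinement.
* **Scalar trimer evidence** — thermodynamic-integration bookkeeping
  (ΔΔG = ΔG_bound − ΔG_solvation with quadrature error propagation), the
  shifted Lennard-Jones 12-6 potential, and rigid-volume monomer-capacity
  bounds (four monomers fit the toroid's bounding box, three its cylinder —
  the trimer).
* **Synthetic data generators** — jittered finite P1 lattices with
  vacancies, point-scatterer crystals with DNA rods in the through
  channels, powder-ring detector images and noisy 1D curves, all with
  known ground truth, so the whole chain is testable without downloads.

## Worked example

```r
library(dpslattice)

# the fitted in vitro crystal cell
cell <- unit_cell(83.3, 83.3, 54.2, 60.5, 60.5, 60.5)

# 150 jittered trimer centres (sigma = 1.5 A, 5% vacancies), as read off a
# tomographic map, then lattice recovery
centers <- generate_lattice_centers(cell, c(6, 6, 5), jitter_sigma = 1.5,
                                    vacancy_rate = 0.05, n_max = 150, seed = 42)
infer_lattice(centers)
#> Lattice fit (P1)
#>   a = 83.04 +/- 2.16   b = 83.00 +/- 1.94   c = 53.97 +/- 2.31  [A]
#>   alpha = 60.21 +/- 1.85   beta = 60.47 +/- 1.91   gamma = 60.48 +/- 1.39  [deg]
#>   673 neighbour vectors used, RMS residual 3.74 A
```

The recovered constants sit inside the published uncertainties
(±3.2 Å, ±2.7 Å, ±4°). The cell's reflections index every experimental
SAXS peak:

```r
refl <- enumerate_reflections(cell, d_min = 30)
match_peaks(refl$d, c(69.6, 54.5, 45.0, 34.4))
#> peak match: 4 of 4 experimental peaks matched (tolerance 5.0%)
#>  experimental_d model_d rel_diff
#>            69.6   68.44   0.0167
#>            54.5   52.90   0.0293
#>            45.0   44.67   0.0074
#>            34.4   34.22   0.0052
```

And the scalar analyses give the trimer its thermodynamic and geometric
support:

```r
binding_delta_g(ti_record(-1787.7, -1903.16, 27.7, 32.05, "Dps-type pore"))$ddG
#> [1] -115.46        # kJ/mol; ferritin-like pore gives -185.98
monomer_capacity(70, 44, c(58, 25, 35), "box")       # 4 monomers at most
monomer_capacity(70, 44, c(58, 25, 35), "cylinder")  # 3 -> a trimer
```

`run_pipeline(demo_config(seed = 1))` chains everything end to end:
generate centres → infer the lattice → simulate the trimer/DNA powder
pattern → render a 2D detector image → reduce it back to d-spacings →
match against the experimental list → energetics, and returns a full run
report (optionally writing CSV/PDB/TIFF/JSON artefacts).

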