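Package: dpslattice
Title: Lattice Inference and Powder-Pattern Analysis for Dps-DNA Protein Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising intracellular protein-DNA crystals of the
    bacterial Dps protein from oligomer-centre coordinates and small-angle
    X-ray scattering (SAXS) data. Provides triclinic unit-cell mathematics
    (metric tensors, d-spacings, reflection enumeration, Bragg conversions),
    inference of P1 lattice constants from point clouds via pair-distance and
    pair-angle distribution functions with neighbour-vector clustering,
    simulation of 1D powder diffraction patterns from point-scatterer crystal
    models with Scherrer size broadening, reduction of 2D powder detector
    images by azimuthal averaging with iterative-clipping background
    estimation and Bragg peak picking, and the scalar thermodynamic and
    volume-packing analyses that support the assignment of the crystal-forming
    unit as a protein trimer. A synthetic-data module generates every input
    the pipeline consumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
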