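test_that("lattice centre generation places exact nodes without noise", {
  cubic <- unit_cell(10, 10, 10, 90, 90, 90)
  cs <- generate_lattice_centers(cubic, c(2, 2, 2), jitter_sigma = 0,
                                 vacancy_rate = 0)
  expect_equal(nrow(cs$points), 8L)
  want <- as.matrix(expand.grid(x = c(0, 10), y = c(0, 10), z = c(0, 10)))
  got <- cs$points[do.call(order, as.data.frame(cs$points)), ]
  want <- want[do.call(order, as.data.frame(want)), ]
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
})

test_that("generators are bit-reproducible for a fixed seed", {
  cell <- dps_cell()
  a <- generate_lattice_centers(cell, c(4, 4, 3), 1.5, 0.05, seed = 7)
  b <- generate_lattice_centers(cell, c(4, 4, 3), 1.5, 0.05, seed = 7)
  expect_identical(a$points, b$points)
  c1 <- synthesize_powder_curve(
    data.frame(position = 1.5, area = 10, sigma = 0.02),
    background = c(1, 1, 0.1), grid = seq(0.5, 3, by = 0.005),
    noise = TRUE, seed = 3)
  c2 <- synthesize_powder_curve(
    data.frame(position = 1.5, area = 10, sigma = 0.02),
    background = c(1, 1, 0.1), grid = seq(0.5, 3, by = 0.005),
    noise = TRUE, seed = 3)
  expect_identical(c1$y, c2$y)
})

test_that("nearest-neighbour distance of the generated lattice is |c|", {
  cell <- dps_cell()
  cs <- generate_lattice_centers(cell, c(6, 6, 5), jitter_sigma = 1.5,
                                 vacancy_rate = 0, seed = 5)
  dmat <- as.matrix(dist(cs$points))
  diag(dmat) <- Inf
  nn <- apply(dmat, 1L, min)
  # shortest lattice vector is c (54.2 A); jitter of 1.5 A per axis
  # perturbs each pair distance by ~sqrt(2)*1.5 A
  expect_equal(median(nn), 54.2, tolerance = 0.05)
})

test_that("vacancy handling: empty result errors, n_max caps the count", {
  cubic <- unit_cell(10, 10, 10, 90, 90, 90)
  expect_error(
    generate_lattice_centers(cubic, c(2, 2, 2), 0, vacancy_rate = 0.9999,
                             seed = 1),
    "vacant")
  cs <- generate_lattice_centers(dps_cell(), c(6, 6, 5), 1.5, 0.05,
                                 n_max = 150, seed = 2)
  expect_equal(nrow(cs$points), 150L)
})

test_that("crystal scatterer bookkeeping: counts and rod weights add up", {
  cell <- dps_cell()
  motif <- trimer_motif()
  s1 <- generate_crystal_scatterers(cell, c(1, 1, 1), motif, dna_rod = FALSE)
  expect_equal(nrow(s1$sites), 3L)
  s_off <- generate_crystal_scatterers(cell, c(4, 4, 3), motif, dna_rod = FALSE)
  expect_equal(nrow(s_off$sites), 48L * 3L)
  s_on <- generate_crystal_scatterers(cell, c(4, 4, 3), motif, dna_rod = TRUE,
                                      rod_spacing = 3.4, rod_weight = 0.05)
  n_rod <- nrow(s_on$sites) - nrow(s_off$sites)
  expect_gt(n_rod, 0L)
  expect_equal(sum(s_on$weight) - sum(s_off$weight), n_rod * 0.05,
               tolerance = 1e-12)
  expect_error(
    generate_crystal_scatterers(cell, c(1, 1, 1), motif, dna_rod = TRUE,
                                rod_spacing = 0),
    "rod_spacing")
})

test_that("synthesized curves: normalization, degenerate cases, Poisson mean", {
  grid <- seq(0.2, 4, by = 0.002)
  flat <- synthesize_powder_curve(data.frame(), background = c(0, 0, 0),
                                  grid = grid)
  expect_true(all(flat$y == 0))
  one <- synthesize_powder_curve(
    data.frame(position = 2, area = 1, sigma = 0.05),
    background = c(0, 0, 0), grid = grid)
  expect_equal(sum(one$y) * 0.002, 1, tolerance = 1e-3)
  # Poisson noise preserves the expectation (200-replicate average)
  base <- synthesize_powder_curve(
    data.frame(position = 2, area = 400, sigma = 0.05),
    background = c(0, 0, 100), grid = seq(1, 3, by = 0.01))
  acc <- 0
  for (r in 1:200)
    acc <- acc + synthesize_powder_curve(
      data.frame(position = 2, area = 400, sigma = 0.05),
      background = c(0, 0, 100), grid = seq(1, 3, by = 0.01),
      noise = TRUE, seed = 5000 + r)$y
  avg <- acc / 200
  se <- sqrt(base$y / 200)
  expect_true(all(abs(avg - base$y) < 5 * se))
})

test_that("round trip: four-peak curve at the SAXS d list is recovered by the picker", {
  lam <- 1.542
  pos <- bragg_convert(saxs_d_list, "d_angstrom", "two_theta_deg", lam)
  sig <- size_broadening(pos, lam, 2000)
  grid <- seq(0.8, 3.2, length.out = 3000)
  curve <- synthesize_powder_curve(
    data.frame(position = pos, area = c(1, 0.8, 0.6, 0.5), sigma = sig),
    background = c(0.2, 1.2, 0.02), grid = grid, wavelength = lam)
  baseline <- estimate_background(curve)
  picked <- pick_peaks(curve, baseline, min_prominence = 0.05)
  expect_equal(nrow(picked), 4L)
  expect_equal(sort(picked$d_angstrom, decreasing = TRUE), saxs_d_list,
               tolerance = 0.01)
})

test_that("rendered rings sit at r = distance * tan(two-theta)", {
  geo <- scattering_geometry(1.542, 2000, c(64.5, 64.5), 0.2)
  tt0 <- 0.8
  grid <- seq(0.01, 1.2, length.out = 2000)
  curve <- synthesize_powder_curve(
    data.frame(position = tt0, area = 1, sigma = 0.01),
    background = c(0, 0, 0), grid = grid)
  img <- render_detector_image(curve, geo, image_size = 128)
  r_px <- 2000 * tan(tt0 * pi / 180) / 0.2
  # brightest pixel on the central row should sit a ring radius away
  row <- img$counts[64, ]
  expect_equal(abs(which.max(row) - 64.5), r_px, tolerance = 1.0)
  # flat curve renders a flat image
  flat <- curve1d(c(0.001, 2), c(3, 3), "two_theta_deg", 1.542)
  geo64 <- scattering_geometry(1.542, 2000, c(32.5, 32.5), 0.2)
  fimg <- render_detector_image(flat, geo64, image_size = 64)
  expect_true(all(abs(fimg$counts - 3) < 1e-9))
})

test_that("projection images show the right blob separation and FFT spacing", {
  two <- center_set(rbind(c(0, 0, 0), c(40, 0, 0)))
  pr <- generate_projection_image(two, "z", pixel_size = 2, psf_sigma = 4)
  img <- pr$image
  # two blobs 40 A apart along the first in-plane axis = 20 px
  pk <- as.integer(which(img == max(img), arr.ind = TRUE)[1, ])
  ridge <- img[, pk[2]]
  ord <- order(ridge, decreasing = TRUE)
  # second blob: highest sample at least 10 px from the first
  second <- ord[which(abs(ord - pk[1]) > 10)[1]]
  expect_equal(abs(second - pk[1]) * 2, 40, tolerance = 2)
  # single point gives a single Gaussian blob (unimodal ridge)
  single <- center_set(rbind(c(0, 0, 0), c(0.1, 0, 0)))
  ps <- generate_projection_image(single, "z", 2, 6)
  expect_equal(sum(ps$image >= 0.999 * max(ps$image)), 1L)
})
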