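make_ring_image <- function(tt0 = 1.0, size = 256, noise = FALSE, seed = NULL,
                            area = 1, sigma = 0.02, bg = c(0, 0, 0)) {
  geo <- scattering_geometry(1.542, 2000, rep((size + 1) / 2, 2), 0.2)
  grid <- seq(0.005, 2.2, length.out = 3000)
  curve <- synthesize_powder_curve(
    data.frame(position = tt0, area = area, sigma = sigma),
    background = bg, grid = grid)
  render_detector_image(curve, geo, image_size = size, noise = noise,
                        seed = seed)
}

test_that("azimuthal average is exact on radial images", {
  # uniform image -> flat curve at the uniform value
  geo <- scattering_geometry(1.542, 2000, c(32.5, 32.5), 0.2)
  img <- detector_image(matrix(7, 64, 64), geo)
  cv <- azimuthal_average(img, n_bins = 32)
  expect_true(all(abs(cv$y - 7) < 1e-12))
  # single synthetic ring -> single peak at the generating angle
  img <- make_ring_image(tt0 = 1.0)
  cv <- azimuthal_average(img, n_bins = 256)
  expect_equal(cv$x[which.max(cv$y)], 1.0, tolerance = 0.01)
  # binning error shrinks as bins double (smooth radial profile)
  smooth_geo <- scattering_geometry(1.542, 2000, c(128.5, 128.5), 0.2)
  n <- 256
  px <- matrix(rep(1:n, each = n), n); py <- matrix(rep(1:n, n), n)
  r <- sqrt((px - 128.5)^2 + (py - 128.5)^2) * 0.2
  tt <- atan(r / 2000) * 180 / pi
  simg <- detector_image(exp(-tt), smooth_geo)
  err_for <- function(nb) {
    cv <- azimuthal_average(simg, n_bins = nb)
    mean(abs(cv$y - exp(-cv$x)))
  }
  expect_lt(err_for(128), err_for(32))
})

test_that("masking changes pixel counts but not the peak position", {
  img <- make_ring_image(tt0 = 1.0)
  mask <- matrix(FALSE, nrow(img$counts), ncol(img$counts))
  mask[, 1:(ncol(mask) / 2)] <- TRUE     # mask half the detector
  masked <- detector_image(img$counts, img$geometry, mask)
  c_full <- azimuthal_average(img, 128)
  c_half <- azimuthal_average(masked, 128)
  expect_equal(c_half$x[which.max(c_half$y)], c_full$x[which.max(c_full$y)],
               tolerance = 1e-9)
  np_full <- attr(c_full, "n_pixels")
  np_half <- attr(c_half, "n_pixels")
  mid <- np_full > 100
  expect_true(all(np_half[mid] / np_full[mid] > 0.3 &
                  np_half[mid] / np_full[mid] < 0.7))
  expect_error(azimuthal_average(
    detector_image(img$counts, img$geometry,
                   matrix(TRUE, nrow(img$counts), ncol(img$counts)))),
    "masked")
})

test_that("background estimation clips peaks but preserves smooth decay", {
  x <- seq(0.2, 3, length.out = 600)
  smooth <- curve1d(x, 5 * x^-1.3 + 0.2, "two_theta_deg", 1.542)
  base <- estimate_background(smooth, window = 15, iterations = 30)
  expect_true(all(base$y <= smooth$y + 1e-12))
  expect_lt(max(abs(base$y - smooth$y) / smooth$y), 0.01)
  # power law + 4 Gaussian peaks: baseline recovers the power law away
  # from the peak cores
  pos <- bragg_convert(saxs_d_list, "d_angstrom", "two_theta_deg", 1.542)
  spik <- curve1d(x, 5 * x^-1.3 + 0.2 +
                    rowSums(vapply(pos, function(p) 3 * dnorm(x, p, 0.02),
                                   numeric(length(x)))),
                  "two_theta_deg", 1.542)
  base2 <- estimate_background(spik, 15, 30)
  away <- vapply(x, function(xx) all(abs(xx - pos) > 0.12), logical(1))
  truth <- 5 * x^-1.3 + 0.2
  expect_lt(max(abs(base2$y[away] - truth[away]) / truth[away]), 0.03)
  # degenerate cases
  zero <- curve1d(x, rep(0, length(x)), "two_theta_deg", 1.542)
  expect_true(all(estimate_background(zero)$y == 0))
  expect_error(estimate_background(smooth, window = 600), "smaller")
})

test_that("baseline is idempotent: a second pass changes almost nothing", {
  img <- make_ring_image(1.0, bg = c(0.5, 1, 0.05), area = 3)
  cv <- azimuthal_average(img, 256)
  b1 <- estimate_background(cv)
  b2 <- estimate_background(b1)
  expect_lt(max(abs(b2$y - b1$y)) / max(b1$y), 1e-3)
})

test_that("peak picking refines positions and flags unresolved blends", {
  x <- seq(0.5, 2.5, length.out = 2000)
  sig <- 0.02
  one <- curve1d(x, 10 * dnorm(x, 1.3004, sig), "two_theta_deg", 1.542)
  pk <- pick_peaks(one, NULL, min_prominence = 0.05, expected_sigma = sig)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$two_theta_deg, 1.3004, tolerance = 1e-4)
  expect_false(pk$possibly_blended)
  # d and q are mutually consistent
  expect_equal(pk$d_angstrom, 2 * pi / pk$q_inv_angstrom, tolerance = 1e-9)
  # two peaks 0.5 sigma apart merge into one, flagged as possibly blended
  blend <- curve1d(x, 5 * dnorm(x, 1.3 - 0.25 * sig, sig) +
                      5 * dnorm(x, 1.3 + 0.25 * sig, sig),
                   "two_theta_deg", 1.542)
  pb <- pick_peaks(blend, NULL, min_prominence = 0.05, expected_sigma = sig)
  expect_equal(nrow(pb), 1L)
  expect_true(pb$possibly_blended)
  # flat residual -> empty list
  flat <- curve1d(x, rep(2, length(x)), "two_theta_deg", 1.542)
  base <- curve1d(x, rep(2, length(x)), "two_theta_deg", 1.542)
  expect_equal(nrow(pick_peaks(flat, base)), 0L)
})

test_that("peak d-values are invariant to intensity rescaling", {
  img <- make_ring_image(1.0, bg = c(0.3, 1, 0.02), area = 2)
  p1 <- reduce_image(img, n_bins = 256)
  scaled <- detector_image(img$counts * 137, img$geometry)
  p2 <- reduce_image(scaled, n_bins = 256)
  expect_equal(p1$d_angstrom, p2$d_angstrom, tolerance = 1e-9)
})

test_that("render -> reduce closes the loop on the four-peak SAXS model", {
  lam <- 1.542
  pos <- bragg_convert(saxs_d_list, "d_angstrom", "two_theta_deg", lam)
  sig <- size_broadening(pos, lam, 2000)
  grid <- seq(0.005, 3.2, length.out = 4000)
  curve <- synthesize_powder_curve(
    data.frame(position = pos, area = c(1, 0.8, 0.6, 0.5) * 2e4, sigma = sig),
    background = c(2e3, 1, 100), grid = grid, wavelength = lam)
  geo <- scattering_geometry(lam, 2000, c(512.5, 512.5), 0.2)
  img <- render_detector_image(curve, geo, image_size = 1024,
                               noise = TRUE, seed = 99)
  peaks <- reduce_image(img, n_bins = 512, min_prominence = 0.05)
  got <- sort(peaks$d_angstrom, decreasing = TRUE)
  expect_equal(length(got), 4L)
  expect_equal(got, saxs_d_list, tolerance = 0.02)
  # determinism for a fixed seed
  img2 <- render_detector_image(curve, geo, image_size = 1024,
                                noise = TRUE, seed = 99)
  peaks2 <- reduce_image(img2, n_bins = 512, min_prominence = 0.05)
  expect_identical(peaks$d_angstrom, peaks2$d_angstrom)
})

test_that("noise-only images yield no confident peak", {
  geo <- scattering_geometry(1.542, 2000, c(128.5, 128.5), 0.2)
  set.seed(77)
  img <- detector_image(matrix(rpois(256^2, 50), 256, 256), geo)
  peaks <- reduce_image(img, n_bins = 128, min_prominence = 0.6)
  expect_equal(nrow(peaks), 0L)
})
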