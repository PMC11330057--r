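oct_fixture <- function(depth = 1.069, noise = 0, seed = 1L, ...) {
  make_oct_phantom(phantom_config(modality = "oct_bscan",
                                  oct_lesion_depth_true = depth,
                                  noise_sigma = noise, seed = seed, ...))
}

test_that("median despeckle matches the explicit neighbourhood oracle", {
  set.seed(7)
  x <- matrix(runif(16 * 16), 16, 16)
  for (k in c(3L, 5L)) {
    expect_equal(despeckle(x, k), oracle_median_filter(x, k))
  }
  expect_identical(despeckle(x, 1L), x)
  expect_error(despeckle(x, 2L), "odd")

  spike <- matrix(0, 3, 3); spike[2, 2] <- 1
  expect_equal(despeckle(spike, 3L), matrix(0, 3, 3))
})

test_that("median filter is idempotent on piecewise-constant interiors", {
  x <- matrix(0.2, 20, 20)
  x[8:20, ] <- 0.8
  once <- despeckle(x, 3L)
  expect_equal(despeckle(once, 3L), once)
})

test_that("surface normal is vertical for a flat surface, 45 deg for a tilt", {
  flat <- oct_fixture()
  sn <- surface_normal(flat$bscan, 60)
  expect_equal(sn$direction, c(1, 0), tolerance = 1e-9)
  expect_lt(sn$angle_deg, 1e-6)
  expect_equal(sn$origin[1], 40, tolerance = 0.5)

  # equal axial/lateral scales and a 1 px/px slope: normal at 45 degrees
  tilted <- make_oct_phantom(phantom_config(
    modality = "oct_bscan", image_height = 200L, image_width = 80L,
    oct_axial_extent_mm = 200 * 0.05, mm_per_pixel = 0.05,
    oct_surface_row = 20L, oct_surface_slope = 1, noise_sigma = 0,
    oct_lesion_depth_true = NA
  ))
  sn45 <- surface_normal(tilted$bscan, 40)
  expect_equal(sn45$angle_deg, 45, tolerance = 2)

  # moderate tilt with speckle: recovered within 2 degrees
  sloped <- make_oct_phantom(phantom_config(
    modality = "oct_bscan", image_height = 200L, image_width = 80L,
    oct_axial_extent_mm = 200 * 0.05, mm_per_pixel = 0.05,
    oct_surface_row = 20L, oct_surface_slope = 0.5, noise_sigma = 0.1,
    oct_lesion_depth_true = NA, seed = 5L
  ))
  snm <- surface_normal(despeckle(sloped$bscan, 3), 40)
  expect_equal(snm$angle_deg, atan(0.5) * 180 / pi, tolerance = 2)
})

test_that("ruler profiles average correctly", {
  b <- bscan(matrix(0.42, 60, 60), 0.02, 0.02)
  prof <- ruler_profile(b, origin = c(5, 30), direction = c(1, 0))
  expect_true(all(abs(prof$intensity - 0.42) < 1e-12))

  # linear ramp: symmetric disk weights cancel, centre value is returned
  ramp <- bscan(matrix(rep(seq(0, 1, length.out = 60), each = 60), 60, 60),
                0.02, 0.02)
  pr <- ruler_profile(ramp, origin = c(10, 30), direction = c(1, 0))
  centre <- swircaries:::bilinear_sample(ramp$pixels,
                                         10 + pr$distance_mm / 0.02,
                                         rep(30, nrow(pr)))
  expect_equal(pr$intensity, centre, tolerance = 1e-9)

  # dense brute-force oracle for the disk average on a smooth field
  f <- function(r, c) 0.3 + 0.004 * r + 0.002 * c + 0.0001 * r * c
  px <- outer(1:60, 1:60, f)
  bf <- bscan(px, 0.02, 0.02)
  pr2 <- ruler_profile(bf, origin = c(8, 25), direction = c(1, 0),
                       disk_diameter_um = 100, step_um = 20)
  i <- 11 # an interior sample
  d_mm <- pr2$distance_mm[i]
  offs <- seq(-0.05, 0.05, length.out = 2001)
  oracle <- mean(swircaries:::bilinear_sample(
    px, rep(8 + d_mm / 0.02, 2001), 25 + offs / 0.02
  ))
  expect_equal(pr2$intensity[i], oracle, tolerance = 1e-6)

  # monotone decay stays monotone in the profile
  dec <- bscan(matrix(rep(exp(-seq(0, 3, length.out = 80)), 40), 80, 40),
               0.02, 0.02)
  prd <- ruler_profile(dec, origin = c(1, 20), direction = c(1, 0))
  expect_true(all(diff(prd$intensity) < 0))
})

test_that("depth is the inter-minima distance over the refractive index", {
  # synthetic profile with sharp minima at 0.20 and 1.25 mm optical
  d <- seq(0, 2, by = 0.01)
  intensity <- 0.5 + 0.3 * pmin(abs(d - 0.20), 0.4) +
    0.3 * pmin(abs(d - 1.25), 0.4)
  prof <- tibble::tibble(distance_mm = d, intensity = intensity)
  attr(prof, "refractive_index") <- 1.6
  class(prof) <- c("ruler_profile", class(prof))
  m <- measure_depth(prof, smooth_window = 1L)
  expect_true(m$detected)
  expect_equal(m$depth_mm, (1.25 - 0.20) / 1.6, tolerance = 1e-9)
  expect_equal(measure_depth(prof, smooth_window = 1L,
                             correct_index = FALSE)$depth_mm,
               1.05, tolerance = 1e-9)

  flat <- prof
  flat$intensity <- rep(0.5, nrow(flat))
  expect_error(measure_depth(flat), "degenerate")
})

test_that("noise-free phantom depth is recovered within one axial pixel", {
  ph <- oct_fixture(depth = 1.069)
  m <- oct_lesion_depth(ph$bscan)
  expect_true(m$detected)
  axial_px_physical <- ph$bscan$mm_axial_optical / 1.6
  expect_lt(abs(m$depth_mm - 1.069), axial_px_physical)
})

test_that("lesion-free scans yield no detection (banding guard)", {
  for (seed in 1:5) {
    ph <- oct_fixture(depth = NA, noise = 0.15, seed = seed)
    expect_false(oct_lesion_depth(ph$bscan)$detected)
  }
  # noise-free banding-only scan as well
  ph0 <- oct_fixture(depth = NA, noise = 0)
  expect_false(oct_lesion_depth(ph0$bscan)$detected)
})

test_that("depth is invariant to global intensity scaling", {
  ph <- oct_fixture(depth = 1.4, noise = 0.1, seed = 9L)
  m1 <- oct_lesion_depth(ph$bscan)
  scaled <- ph$bscan
  scaled$pixels <- scaled$pixels * 0.37
  m2 <- oct_lesion_depth(scaled)
  expect_equal(m2$depth_mm, m1$depth_mm)
})

test_that("physical range divides the air range by the refractive index", {
  expect_equal(max_physical_range(7, 1.6), 4.4)
  expect_equal(max_physical_range(7, 1), 7)
  expect_equal(max_physical_range(10, 1.6), 6.3)
  b <- oct_fixture()$bscan
  expect_equal(max_physical_range(b), 4.4)
})
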