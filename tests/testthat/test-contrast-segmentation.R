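make_img <- function(px, modality = "reflectance", mm = NA_real_) {
  intensity_image(px, modality, mm)
}

simple_roi <- function(dim, sound_cells, contact_cells) {
  sound <- matrix(FALSE, dim[1], dim[2]); sound[sound_cells] <- TRUE
  contact <- matrix(FALSE, dim[1], dim[2]); contact[contact_cells] <- TRUE
  roi_set(sound, contact)
}

test_that("contrast transforms match the printed formulas", {
  px <- matrix(100, 4, 4)
  px[2, 2] <- 125 # reflectance: (125 - 100) / 125 = 0.2
  roi <- simple_roi(c(4, 4), cbind(4, 1:4), cbind(1, 1:4))
  cm <- contrast_map(make_img(px, "reflectance"), roi)
  expect_equal(cm$i_s, 100)
  expect_equal(cm$values[2, 2], 0.2)
  expect_equal(cm$values[3, 3], 0)

  px2 <- matrix(100, 4, 4)
  px2[2, 2] <- 73  # transillumination: (100 - 73) / 100 = 0.27
  px2[3, 3] <- 100 # identity case -> 0
  for (mod in c("occlusal_trans", "proximal_trans")) {
    cmt <- contrast_map(make_img(px2, mod), roi)
    expect_equal(cmt$values[2, 2], 0.27)
    expect_equal(cmt$values[3, 3], 0)
  }
})

test_that("i_s is the mean of the sound region (median behind a flag)", {
  px <- matrix(c(90, 110, rep(50, 14)), 4, 4)
  roi <- simple_roi(c(4, 4), cbind(c(1, 2), c(1, 1)), cbind(4, 1:4))
  expect_equal(contrast_map(make_img(px, "occlusal_trans"), roi)$i_s, 100)
  expect_equal(contrast_map(make_img(px, "occlusal_trans"), roi,
                            stat = "median")$i_s, 100)
  expect_error(contrast_map(make_img(matrix(0, 4, 4), "occlusal_trans"), roi),
               "positive")
})

test_that("zero-intensity reflectance pixels are flagged and never masked", {
  px <- matrix(100, 4, 4)
  px[1, 1] <- 0
  roi <- simple_roi(c(4, 4), cbind(4, 1:4), cbind(2, 1:4))
  cm <- contrast_map(make_img(px, "reflectance"), roi)
  expect_true(cm$excluded[1, 1])
  expect_identical(cm$values[1, 1], -Inf)
  expect_false(threshold_mask(cm, -1e9)[1, 1])
  expect_true(all(threshold_mask(cm, -1e9)[-1]))
})

test_that("threshold keeps the boundary and behaves monotonically", {
  vals <- matrix(c(0, 0.05, 0.1, 0.3), 2, 2)
  cm <- structure(list(values = vals, i_s = 1, modality = "reflectance",
                       excluded = matrix(FALSE, 2, 2)),
                  class = "contrast_map")
  m <- threshold_mask(cm, 0.1)
  expect_identical(as.vector(m), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(sum(threshold_mask(cm, 0)), 4L)
  # raising the threshold never enlarges the mask
  ph <- tiny_phantom(noise = 0.01)
  cm2 <- contrast_map(ph$image, ph$roi)
  prev <- threshold_mask(cm2, 0.05)
  for (t in c(0.1, 0.15, 0.3, 0.6)) {
    cur <- threshold_mask(cm2, t)
    expect_true(all(prev[cur]))
    prev <- cur
  }
})

test_that("noise-free phantoms are segmented exactly (contrast closure)", {
  for (mod in c("reflectance", "occlusal_trans", "proximal_trans")) {
    for (c_true in c(0.13, 0.2, 0.22, 0.27)) {
      ph <- tiny_phantom(modality = mod, c_true = c_true)
      cm <- contrast_map(ph$image, ph$roi)
      expect_equal(unique(cm$values[ph$truth$lesion_mask]), c_true,
                   tolerance = 1e-12)
      seg <- segment_lesion(ph$image, ph$roi)
      expect_true(seg$detected)
      expect_identical(seg$mask, ph$truth$lesion_mask)
      expect_lt(abs(seg$mean_contrast - c_true), 1e-9)
    }
  }
})

test_that("components away from the contact are discarded", {
  mask <- matrix(FALSE, 10, 12)
  mask[4:6, 6:8] <- TRUE   # lesion blob, touches contact at column 5
  mask[1:2, 11:12] <- TRUE # distant specular blob
  roi <- simple_roi(c(10, 12), cbind(10, 1:3), cbind(1:10, 5))
  seg <- select_lesion(mask, roi)
  expect_true(seg$detected)
  expect_identical(sum(seg$mask), 9L)
  expect_false(any(seg$mask[1:2, 11:12]))

  empty <- select_lesion(matrix(FALSE, 10, 12), roi)
  expect_false(empty$detected)
  expect_identical(empty$area_px, 0L)
  expect_true(is.na(empty$mean_contrast))
})

test_that("adjoining is 8-connected: a diagonal touch counts", {
  mask <- matrix(FALSE, 6, 6)
  mask[3, 4] <- TRUE # diagonal neighbour of contact pixel (2, 3)
  roi <- simple_roi(c(6, 6), cbind(6, 1:2), cbind(2, 3))
  expect_true(select_lesion(mask, roi, connectivity = 8)$detected)
  expect_false(select_lesion(mask, roi, connectivity = 4)$detected)
})

test_that("artifacts never change detection or lesion metrics", {
  base <- make_swir_phantom(phantom_config(
    modality = "reflectance", lesion_contrast_true = 0.2, noise_sigma = 0,
    specular_spots = list()
  ))
  spotted <- make_swir_phantom(phantom_config(
    modality = "reflectance", lesion_contrast_true = 0.2, noise_sigma = 0,
    specular_spots = list(list(center = c(30, 40), radius = 8,
                               intensity = 0.98),
                          list(center = c(120, 30), radius = 5,
                               intensity = 0.9))
  ))
  s1 <- segment_lesion(base$image, base$roi)
  s2 <- segment_lesion(spotted$image, spotted$roi)
  expect_identical(s1$mask, s2$mask)
  expect_equal(s1$mean_contrast, s2$mean_contrast)
  expect_equal(s1$area_px, s2$area_px)
})

test_that("detection flips with contrast level across seeded phantoms", {
  detected_at <- function(c_true) {
    vapply(1:50, function(i) {
      ph <- tiny_phantom(modality = "occlusal_trans", c_true = c_true,
                         noise = NULL, seed = 1000L + i)
      segment_lesion(ph$image, ph$roi)$detected
    }, logical(1))
  }
  expect_equal(mean(detected_at(0.2)), 1.0)
  expect_equal(mean(detected_at(0.05)), 0.0)
})

test_that("lesion metrics follow the geometry", {
  # 3x3 square of contrast 0.2 beside a vertical contact line
  px <- matrix(100, 8, 8)
  px[3:5, 4:6] <- 80 # trans contrast 0.2
  roi <- simple_roi(c(8, 8), cbind(8, 5:8), cbind(1:8, 3))
  img <- make_img(px, "occlusal_trans", mm = 0.1)
  seg <- segment_lesion(img, roi)
  expect_identical(seg$area_px, 9L)
  expect_equal(seg$mean_contrast, 0.2)
  expect_equal(seg$depth_mm, 0.3)
  expect_equal(seg$area_mm2, 9 * 0.01)

  # phantom area within a 2-pixel boundary ring of the truth
  ph <- tiny_phantom(c_true = 0.3, noise = 0.01)
  seg2 <- segment_lesion(ph$image, ph$roi)
  ring <- sum(swircaries:::dilate_mask(swircaries:::dilate_mask(
    ph$truth$lesion_mask)) ) - ph$truth$true_area_px
  expect_lt(abs(seg2$area_px - ph$truth$true_area_px), ring)

  expect_warning(
    segment_lesion(make_img(px, "occlusal_trans"), roi),
    "pixels only"
  )
})

test_that("pixel calibration attaches the reference-target scale", {
  img <- make_img(matrix(0.5, 4, 4))
  expect_equal(calibrate_px_to_mm(img, 10, 200)$mm_per_pixel, 0.05)
  expect_error(calibrate_px_to_mm(img, 10, 0), "positive")
  expect_error(calibrate_px_to_mm(img, -1, 10), "positive")
})
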