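test_that("neighbourhood features: median suppresses speckle, sd flags texture", {
  # constant image -> sd identically 0, median equal to the constant
  f <- neighborhood_features(flat_image(0.5), 3)
  expect_equal(max(abs(f$median - 0.5)), 0, tolerance = 1e-4)
  expect_equal(max(f$sd), 0, tolerance = 1e-4)
  # 5x5 image, all 10 except centre 255, radius 1: median at centre = 10
  m <- matrix(10 / 255, 5, 5); m[3, 3] <- 1
  f2 <- neighborhood_features(m, 1)
  expect_equal(f2$median[3, 3], 10 / 255, tolerance = 1e-4)
  # product channel is the elementwise product of the other two
  img <- matrix(runif(64 * 64), 64, 64)
  f3 <- neighborhood_features(img, 2)
  expect_equal(f3$product, f3$median * f3$sd, tolerance = 1e-12)
  expect_error(neighborhood_features(matrix(0.5, 10, 10), 6), "radius")
})

test_that("thresholding recovers planted vacuoles and is monotone", {
  p <- marrow_image_params(width_px = 320, height_px = 320, n_adipocytes = 10,
                           background_noise_sd = 0, median_diameter_um = 45,
                           seed = 12)
  sim <- gen_marrow_image(p)
  f <- neighborhood_features(sim$image, 3)
  mask <- threshold_adipocytes(f, sim$roi)
  tm <- sim$truth$label_map > 0
  jac <- sum(mask & tm) / sum(mask | tm)
  expect_gte(jac, 0.98)
  # raising the luminance threshold can only shrink the mask
  sp <- segmentation_params(luminance_threshold = 0.80, texture_threshold = "auto")
  m1 <- threshold_adipocytes(f, sim$roi, sp)
  sp2 <- segmentation_params(luminance_threshold = 0.90, texture_threshold = "auto")
  m2 <- threshold_adipocytes(f, sim$roi, sp2)
  expect_true(all(m1[m2]))
  # empty ROI -> error; degenerate histogram with "auto" -> instructive error
  expect_error(threshold_adipocytes(f, matrix(FALSE, 320, 320)), "ROI is empty")
  fc <- neighborhood_features(flat_image(0.5, 32), 3)
  expect_error(threshold_adipocytes(fc, matrix(TRUE, 32, 32)), "fixed threshold")
})

test_that("cluster separation splits touching disks and conserves area", {
  # single disk -> one label
  d1 <- disk_label(20)
  l1 <- separate_clusters(d1, 1, 15)
  expect_equal(max(l1), 1)
  # two disks radius 30 um overlapping ~20% -> 2 labels, centroids within 5 um
  n <- 140
  m <- matrix(0L, n, n)
  g <- expand.grid(r = 1:n, c = 1:n)
  c1 <- c(70, 50); c2 <- c(70, 50 + 2 * 30 - 0.2 * 30)
  m[(g$r - c1[1])^2 + (g$c - c1[2])^2 <= 30^2 |
      (g$r - c2[1])^2 + (g$c - c2[2])^2 <= 30^2] <- 1L
  l2 <- separate_clusters(m, 1, 15)
  expect_equal(max(l2), 2)
  expect_equal(sum(l2 > 0), sum(m))            # mask conservation, exact
  for (cc in list(c1, c2)) {
    best <- Inf
    for (l in 1:2) {
      idx <- which(l2 == l, arr.ind = TRUE)
      best <- min(best, sqrt(sum((colMeans(idx) - cc)^2)))
    }
    expect_lt(best, 5)
  }
  # disjoint blobs -> label count equals component count; empty mask is fine
  m3 <- matrix(0L, 60, 60); m3[5:15, 5:15] <- 1L; m3[40:50, 40:50] <- 1L
  expect_equal(max(separate_clusters(m3, 1, 15)), 2)
  expect_true(all(separate_clusters(matrix(0L, 10, 10), 1, 15) == 0L))
})

test_that("shape filter reproduces closed-form geometry oracles", {
  sp <- segmentation_params(min_area_um2 = 10, max_area_um2 = 1e7,
                            min_form_factor = 0)
  # rasterised disks: form factor within discretisation tolerance of 1
  for (r in c(10, 30, 60)) {
    ob <- shape_filter(disk_label(r), 1, sp)
    expect_equal(nrow(ob), 1)
    expect_gte(ob$form_factor, 0.90)
    expect_lte(ob$form_factor, 1.05)
    expect_equal(ob$area_um2, sum(disk_label(r)), tolerance = 1e-12)
  }
  # 100x4 rectangle: closed form 4*pi*400/208^2, elongated -> dropped by default
  ob <- shape_filter(rect_label(4, 100), 1, sp)
  expect_lt(abs(ob$form_factor - 4 * pi * 400 / 208^2), 1e-3)
  expect_equal(nrow(shape_filter(rect_label(4, 100), 1, segmentation_params())), 0)
  # area thresholds remove objects regardless of shape
  small <- disk_label(5)
  expect_equal(nrow(shape_filter(small, 1, segmentation_params())), 0)   # < 200 um2
  expect_error(shape_filter(disk_label(5), 0), "pixel_size_um")
})

test_that("morphometry is exact arithmetic over the ROI", {
  objects <- data.frame(area_um2 = rep(100, 10))
  roi <- list(mask = matrix(TRUE, 100, 100), pixel_size_um = sqrt(2e6) / 100)
  s <- morphometry(objects, roi)    # ROI area = 2 mm2
  expect_equal(s$roi_area_mm2, 2)
  expect_equal(s$density_per_mm2, 5)
  expect_equal(s$n_adipocytes, 10)
  s0 <- morphometry(objects[0, , drop = FALSE], roi)
  expect_equal(s0$n_adipocytes, 0)
  expect_equal(s0$density_per_mm2, 0)
  expect_length(s0$sizes_um2, 0)
  expect_error(morphometry(objects, list(mask = matrix(FALSE, 4, 4),
                                         pixel_size_um = 1)), "zero")
})

test_that("full segmentation is scale-equivariant in physical units", {
  p1 <- marrow_image_params(width_px = 256, height_px = 256, pixel_size_um = 1,
                            n_adipocytes = 6, median_diameter_um = 40, seed = 21)
  p2 <- marrow_image_params(width_px = 512, height_px = 512, pixel_size_um = 0.5,
                            n_adipocytes = 6, median_diameter_um = 40, seed = 21)
  s1 <- segment_adipocytes(gen_marrow_image(p1)$image, gen_marrow_image(p1)$roi)
  s2 <- segment_adipocytes(gen_marrow_image(p2)$image, gen_marrow_image(p2)$roi)
  expect_equal(s1$summary$n_adipocytes, s2$summary$n_adipocytes)
  expect_equal(s1$summary$density_per_mm2, s2$summary$density_per_mm2,
               tolerance = 0.02)
  expect_equal(mean(s1$summary$sizes_um2), mean(s2$summary$sizes_um2),
               tolerance = 0.02)
})

test_that("stricter shape criteria never increase the object count", {
  p <- marrow_image_params(width_px = 320, height_px = 320, n_adipocytes = 10,
                           median_diameter_um = 45, seed = 33)
  sim <- gen_marrow_image(p)
  f <- neighborhood_features(sim$image, 3)
  mask <- threshold_adipocytes(f, sim$roi)
  labels <- separate_clusters(mask, 1, 15)
  base <- nrow(shape_filter(labels, 1, segmentation_params()))
  stricter_ff <- nrow(shape_filter(labels, 1, segmentation_params(min_form_factor = 0.8)))
  narrower <- nrow(shape_filter(labels, 1, segmentation_params(
    min_area_um2 = 800, max_area_um2 = 4000)))
  expect_lte(stricter_ff, base)
  expect_lte(narrower, base)
})
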