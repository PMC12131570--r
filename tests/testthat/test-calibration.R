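test_that("coin detection recovers generative center and radius", {
  img <- phenokit:::blank_rgb(300, 300)
  img <- phenokit:::paint_rgb(img, phenokit:::ellipse_mask(300, 300, c(100, 100), 50, 50),
                              c(0.6, 0.6, 0.6))
  d <- detect_coin(img, min_radius_px = 20)
  expect_lt(max(abs(d$center - c(100, 100))), 1)
  expect_lt(abs(d$radius - 50) / 50, 0.02)
  expect_gt(d$circularity, 0.85)
  expect_lte(d$circularity, 1)
})

test_that("coin detection fails cleanly on an empty image", {
  img <- phenokit:::blank_rgb(100, 100)
  expect_error(detect_coin(img), class = "pheno_coin_not_found")
})

test_that("disc beats ellipse on circularity, matching a brute-force oracle", {
  img <- phenokit:::blank_rgb(300, 420)
  disc <- phenokit:::ellipse_mask(300, 420, c(150, 100), 50, 50)
  ell <- phenokit:::ellipse_mask(300, 420, c(150, 300), 60, 20)
  img <- phenokit:::paint_rgb(img, disc, c(0.7, 0.7, 0.7))
  img <- phenokit:::paint_rgb(img, ell, c(0.7, 0.7, 0.7))
  # oracle: the rasterized disc really is more circular than the ellipse
  expect_gt(circularity_bruteforce(disc), circularity_bruteforce(ell))
  d <- detect_coin(img, min_radius_px = 10, circularity_min = 0.3)
  expect_lt(max(abs(d$center - c(150, 100))), 1.5)
})

test_that("scale_from_coin arithmetic and validation", {
  d <- structure(list(center = c(1, 1), radius = 125, circularity = 1), class = "pheno_circle")
  expect_equal(scale_from_coin(d, 25)$mm_per_px, 0.1)
  d$radius <- 50
  expect_equal(scale_from_coin(d, 25)$mm_per_px, 0.25)
  expect_error(scale_from_coin(d, 0), class = "pheno_invalid_parameter")
})

test_that("coin scale is recovered within 2% over many random scenes", {
  errs <- vapply(1:50, function(s) {
    radius <- sample(20:90, 1)
    sc <- gen_seed_tray(n_seeds = 10, coin_radius_px = radius,
                        image_size = c(420, 420), seed = 1000 + s)
    cal <- scale_from_coin(detect_coin(sc$image), 25)
    abs(cal$mm_per_px - sc$gt$mm_per_px) / sc$gt$mm_per_px
  }, numeric(1))
  expect_lt(max(errs), 0.02)
})

test_that("convert_units covers all kinds and round-trips exactly", {
  cal <- calibration(0.1, "coin")
  expect_equal(as.numeric(convert_units(100, "length", cal)), 10)
  expect_equal(as.numeric(convert_units(400, "area", calibration(0.5, "manual"))), 100)
  expect_equal(as.numeric(convert_units(1e-4, "count_density", calibration(1, "coin"))), 100)
  for (kind in c("length", "area", "count_density")) {
    x <- 137.5
    back <- convert_units(as.numeric(convert_units(x, kind, cal)), kind, cal, inverse = TRUE)
    expect_equal(as.numeric(back), x)
  }
  un <- convert_units(42, "length", calibration())
  expect_false(attr(un, "calibrated"))
  expect_equal(as.numeric(un), 42)
})

test_that("rectangular marker corners are found within 2 px (axis-aligned and warped)", {
  # axis-aligned rectangle
  img <- phenokit:::blank_rgb(300, 400)
  img[101:200, 101:300, ] <- 1
  mk <- detect_rect_marker(img, real_width_m = 2, real_height_m = 1)
  want <- rbind(c(101, 101), c(101, 300), c(200, 300), c(200, 101))
  for (i in 1:4)
    expect_lt(min(sqrt((want[, 1] - mk$corners[i, "row"])^2 +
                       (want[, 2] - mk$corners[i, "col"])^2)), 2)
  # known projective warp
  wp <- gen_wheat_plot(seed = 5, rotation_deg = 5, perspective = c(4e-5, -3e-5))
  mk2 <- detect_rect_marker(wp$image, real_width_m = 1, real_height_m = 1)
  gtc <- wp$gt$corners_image
  for (i in 1:4)
    expect_lt(min(sqrt((gtc[, 1] - mk2$corners[i, "col"])^2 +
                       (gtc[, 2] - mk2$corners[i, "row"])^2)), 2)
  # no white region
  expect_error(detect_rect_marker(phenokit:::blank_rgb(50, 50)),
               class = "pheno_marker_not_found")
})

test_that("rectification maps marker corners to the target rectangle and is idempotent", {
  wp <- gen_wheat_plot(seed = 6, rotation_deg = 8, perspective = c(5e-5, 3e-5))
  mk <- detect_rect_marker(wp$image, real_width_m = 1, real_height_m = 1)
  rec <- rectify_from_marker(wp$image, mk)
  src <- cbind(mk$corners[, "col"], mk$corners[, "row"])
  mapped <- phenokit:::apply_homography(rec$homography, src)
  tgt <- cbind(rec$target_corners[, "col"], rec$target_corners[, "row"])
  expect_lt(max(sqrt(rowSums((mapped - tgt)^2))), 1)
  # idempotency on the already-rectified image
  mk2 <- detect_rect_marker(rec$image, real_width_m = 1, real_height_m = 1)
  rec2 <- rectify_from_marker(rec$image, mk2)
  src2 <- cbind(mk2$corners[, "col"], mk2$corners[, "row"])
  moved <- phenokit:::apply_homography(rec2$homography, src2)
  expect_lt(max(sqrt(rowSums((moved - src2)^2))), 1)
  # collinear corners are rejected
  bad <- structure(list(
    corners = cbind(row = c(1, 1, 1, 50), col = c(1, 50, 100, 100)),
    area_px = 100, real_width_m = 1, real_height_m = 1), class = "pheno_quad")
  expect_error(rectify_from_marker(wp$image, bad), class = "pheno_invalid_marker")
})

test_that("recovered homography composed with a known warp is near-identity on corners", {
  wp <- gen_wheat_plot(seed = 7, rotation_deg = 5, perspective = c(2e-5, -1.5e-5))
  mk <- detect_rect_marker(wp$image, real_width_m = 1, real_height_m = 1)
  rec <- rectify_from_marker(wp$image, mk)
  # forward-apply the known generative warp to the world corners, then the
  # recovered homography: all four corners must land on one axis-aligned
  # rectangle (the rectified marker); integer-pixel corner snapping allows
  # up to ~2 px residual misalignment
  imgc <- phenokit:::apply_homography(wp$gt$H, wp$gt$corners_world)
  out <- phenokit:::apply_homography(rec$homography, imgc)
  expect_lt(diff(range(out[c(1, 4), 1])), 2)   # left edge x alignment
  expect_lt(diff(range(out[c(2, 3), 1])), 2)   # right edge
  expect_lt(diff(range(out[c(1, 2), 2])), 2)   # top edge y alignment
  expect_lt(diff(range(out[c(3, 4), 2])), 2)   # bottom edge
})
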