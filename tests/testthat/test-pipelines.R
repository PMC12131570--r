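test_that("seed pipeline counts, measures and calibrates a full tray", {
  sc <- gen_seed_tray(n_seeds = 50, coin_radius_px = 100,
                      image_size = c(760, 760), seed = 101)
  r <- run_seed_pheno(sc$image)
  expect_equal(r$traits$count, 50L)
  expect_equal(r$calibration$source, "coin")
  expect_lt(abs(r$calibration$mm_per_px - 0.125) / 0.125, 0.02)
  got <- r$traits$stats$mean[r$traits$stats$trait == "length_px"]
  expect_lt(abs(got - mean(2 * sc$gt$seeds$a)) / mean(2 * sc$gt$seeds$a), 0.02)
  # mm columns consistent with the calibration
  expect_equal(r$records$length_mm, r$records$length_px * r$calibration$mm_per_px)
})

test_that("seed pipeline on a coin-only scene gives zero count with calibration", {
  sc <- gen_seed_tray(n_seeds = 0, seed = 102)
  r <- run_seed_pheno(sc$image)
  expect_equal(r$traits$count, 0L)
  expect_equal(r$calibration$source, "coin")
})

test_that("tomato pipeline counts red fruit only and sizes them", {
  sc <- gen_tomato_scene(n_tomatoes = 12, radius_range = c(40, 80),
                         coin_radius_px = 95, image_size = c(900, 900), seed = 103)
  r <- run_tomato_pheno(sc$image)
  expect_equal(r$traits$count, 12L)
  eqd <- sort(r$records$equivalent_diameter_px)
  gtd <- sort(2 * sc$gt$tomatoes$radius)
  expect_lt(max(abs(eqd - gtd) / gtd), 0.03)
  # green discs are not tomatoes
  img <- phenokit:::blank_rgb(200, 200)
  img <- phenokit:::paint_rgb(img, phenokit:::ellipse_mask(200, 200, c(100, 100), 40, 40),
                              c(0.2, 0.7, 0.2))
  expect_equal(run_tomato_pheno(img)$traits$count, 0L)
  # two tangent red discs are split
  img2 <- phenokit:::blank_rgb(160, 240)
  m <- (phenokit:::ellipse_mask(160, 240, c(80, 80), 40, 40) |
        phenokit:::ellipse_mask(160, 240, c(80, 160), 40, 40))
  img2 <- phenokit:::paint_rgb(img2, m, c(0.9, 0.1, 0.08))
  r2 <- run_tomato_pheno(img2, pheno_config(peak_min_distance = 20))
  expect_equal(r2$traits$count, 2L)
})

test_that("spikelet pipeline: parallel spikelets give near-zero angles; singleton has no axis", {
  sc <- gen_spikelet_ear(n_spikelets = 14, angle_deg = 0, axis_coeffs = c(0, 0, 0),
                         seed = 104)
  r <- run_spikelet_pheno(sc$image)
  expect_equal(r$traits$count, 14L)
  expect_lt(max(r$traits$angles_deg), 2)
  one <- gen_spikelet_ear(n_spikelets = 1, seed = 105)
  r1 <- run_spikelet_pheno(one$image)
  expect_equal(r1$traits$count, 1L)
  expect_null(r1$traits$ear_axis)
})

test_that("canopy pipeline measures shape and color; star is less compact than disc", {
  disc <- gen_canopy("disc", radius = 160, green_fraction = 0.7, seed = 106)
  rd <- run_canopy_pheno(disc$image)
  expect_equal(rd$traits$area_px2, disc$gt$area_px)
  expect_gte(rd$traits$compactness, 0.9)
  expect_lt(abs(rd$traits$green_ratio - disc$gt$green_fraction), 0.02)
  star <- gen_canopy("star", radius = 160, green_fraction = 0.7, seed = 106)
  rs <- run_canopy_pheno(star$image)
  expect_lt(rs$traits$compactness, rd$traits$compactness)
  expect_lt(abs(rs$traits$area_px2 / rd$traits$area_px2 - 1), 0.03)  # equal-area shapes
  # empty scene
  r0 <- run_canopy_pheno(phenokit:::blank_rgb(80, 80))
  expect_equal(r0$traits$count, 0L)
  expect_equal(r0$traits$area_px2, 0)
})

test_that("corn pipeline works from matrix, CSV and rendered image", {
  cl <- gen_corn_lattice(n_rows = 14, n_cols = 30, jitter_frac = 0.1,
                         rotation_deg = 20, seed = 107)
  r <- run_corn_pheno(cl$gt$points)
  expect_equal(r$traits$visible_row_count, 14L)
  expect_equal(r$traits$visible_kernel_count, 420L)
  expect_lt(abs(r$traits$mean_kernels_per_row - 30), 0.5)
  # CSV round-trip
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = cl$gt$points[, 1], y = cl$gt$points[, 2]), f, row.names = FALSE)
  r2 <- run_corn_pheno(f)
  expect_equal(r2$traits$kernels_per_row, r$traits$kernels_per_row)
  unlink(f)
  # single row from points
  one <- cbind(x = seq(0, 300, 10), y = rnorm(31, 0, 1))
  r3 <- run_corn_pheno(one, pheno_config(k_min = 1, k_max = 1))
  expect_equal(r3$traits$visible_row_count, 1L)
  # rendered ear image through the classical blob backend
  clr <- gen_corn_lattice(n_rows = 8, n_cols = 18, jitter_frac = 0.08,
                          render = TRUE, seed = 108)
  r4 <- run_corn_pheno(clr$image)
  expect_equal(r4$traits$visible_row_count, 8L)
  expect_equal(r4$traits$visible_kernel_count, 144L)
  expect_equal(r4$provenance$backend, "classical_blob")
})

test_that("leaf-angle pipeline consumes keypoint tables and matches the direct formula", {
  df <- data.frame(x = c(0, 0, 0, 100), y = c(-50, 100, 0, 100),
                   role = c("A", "B", "C", "L"))
  r <- run_leaf_angle(df)
  expect_equal(r$traits$angle_deg, 45)
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_equal(run_leaf_angle(f)$traits$angle_deg, 45)
  unlink(f)
  # collinear L: zero angle
  df0 <- data.frame(x = c(0, 0, 0, 0), y = c(-50, 100, 0, 60),
                    role = c("A", "B", "C", "L"))
  expect_equal(run_leaf_angle(df0)$traits$angle_deg, 0)
  # both modes against direct computations over random configurations
  withr::with_seed(109, {
    for (i in 1:20) {
      kp <- keypoint_triple(runif(2, 0, 50), runif(2, 50, 100),
                            runif(2, 20, 80), runif(2, 0, 100))
      expect_equal(run_leaf_angle(kp)$traits$angle_deg,
                   angle_at_vertex(kp$C, kp$B, kp$L))
      r2 <- run_leaf_angle(kp, pheno_config(leaf_angle_mode = "stem_axis_leaf"))
      expect_equal(r2$traits$angle_deg, flag_leaf_angle(kp, "stem_axis_leaf"))
    }
  })
})

test_that("wheat-head pipeline: count, density, yield chain, and markerless fallback", {
  wp <- gen_wheat_plot(density_per_m2 = 60, seed = 110, rotation_deg = 4,
                       perspective = c(3e-5, -2e-5))
  r <- run_wheat_head(wp$image, pheno_config(head_weight_g = 1.5))
  expect_equal(r$traits$count, 60L)
  expect_equal(r$traits$density_per_m2, 60)
  expect_equal(r$traits$yield_kg_per_ha, 900)   # 60 * 1.5 g/m2 = 600 g -> 900 kg/ha
  expect_equal(r$calibration$source, "marker")
  # empty marker
  wp0 <- gen_wheat_plot(density_per_m2 = 0, n_outside = 3, seed = 111)
  r0 <- run_wheat_head(wp0$image)
  expect_equal(r0$traits$density_per_m2, 0)
  # no marker: uncalibrated count, no density
  img <- phenokit:::blank_rgb(200, 200)
  img <- phenokit:::paint_rgb(img, phenokit:::ellipse_mask(200, 200, c(60, 60), 12, 12),
                              c(0.8, 0.7, 0.42))
  img <- phenokit:::paint_rgb(img, phenokit:::ellipse_mask(200, 200, c(140, 140), 12, 12),
                              c(0.8, 0.7, 0.42))
  rn <- run_wheat_head(img)
  expect_equal(rn$traits$count, 2L)
  expect_null(rn$traits$density_per_m2)
  expect_equal(rn$calibration$source, "none")
})

test_that("pipelines are deterministic: identical result JSON on repeated runs", {
  sc <- gen_seed_tray(n_seeds = 12, seed = 112)
  j1 <- result_to_json(run_seed_pheno(sc$image))
  j2 <- result_to_json(run_seed_pheno(sc$image))
  expect_identical(as.character(j1), as.character(j2))
  cl <- gen_corn_lattice(n_rows = 8, n_cols = 20, seed = 113)
  k1 <- result_to_json(run_corn_pheno(cl$gt$points))
  k2 <- result_to_json(run_corn_pheno(cl$gt$points))
  expect_identical(as.character(k1), as.character(k2))
})

test_that("counts are invariant to image-wide brightness scaling within 20 percent", {
  sc <- gen_seed_tray(n_seeds = 30, seed = 114)
  base <- run_seed_pheno(sc$image)$traits$count
  for (f in c(0.8, 1.2)) {
    img <- phenokit:::clamp(sc$image * f, 0, 1)
    expect_equal(run_seed_pheno(img)$traits$count, base)
  }
})

test_that("results serialize to valid JSON with provenance", {
  sc <- gen_canopy("disc", seed = 115)
  r <- run_canopy_pheno(sc$image)
  js <- result_to_json(r)
  expect_true(jsonlite::validate(js))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$pipeline, "canopy_pheno")
  expect_true(all(c("version", "seed", "config_hash", "backend") %in%
                  names(parsed$provenance)))
  f <- tempfile(fileext = ".json")
  result_to_json(r, f)
  expect_true(file.exists(f))
  unlink(f)
})
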