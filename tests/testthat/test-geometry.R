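test_that("ransac recovers exact and noisy line directions", {
  pts <- cbind(x = 1:50, y = 1:50)
  lm <- ransac_major_axis(pts, seed = 1)
  expect_equal(as.numeric(lm$direction), c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-9)
  expect_equal(lm$inlier_count, 50L)
  # rasterized ellipse, orientation 25 degrees
  em <- phenokit:::ellipse_mask(200, 200, c(100, 100), 60, 20, 25)
  px <- which(em, arr.ind = TRUE)
  fit <- ransac_major_axis(cbind(x = px[, 2], y = px[, 1]), seed = 3)
  ang <- atan2(fit$direction[2], fit$direction[1]) * 180 / pi
  expect_lt(abs(ang - 25), 3)
  # 90% on-line + 10% outliers, over 20 seeds
  withr::with_seed(10, {
    base <- cbind(x = seq(0, 100, length.out = 90), y = 0.5 * seq(0, 100, length.out = 90))
    out <- cbind(x = runif(10, 0, 100), y = runif(10, -50, 50))
  })
  true_ang <- atan2(0.5, 1) * 180 / pi
  for (s in 1:20) {
    fit <- ransac_major_axis(rbind(base, out), seed = s)
    ang <- atan2(fit$direction[2], fit$direction[1]) * 180 / pi
    expect_lt(abs(ang - true_ang), 2)
  }
  expect_error(ransac_major_axis(matrix(1, 5, 2), seed = 1), class = "pheno_degenerate")
})

test_that("ransac with no outliers agrees with total least squares", {
  withr::with_seed(4, {
    t <- runif(120, 0, 80)
    pts <- cbind(x = t * cos(0.6), y = t * sin(0.6)) +
      matrix(rnorm(240, 0, 0.3), ncol = 2)
  })
  fit <- ransac_major_axis(pts, inlier_tol_px = 3, seed = 5)
  tls <- phenokit:::tls_line(pts)
  a1 <- atan2(fit$direction[2], fit$direction[1]) * 180 / pi
  a2 <- atan2(tls$direction[2], tls$direction[1]) * 180 / pi
  expect_lt(abs(a1 - a2), 0.1)
})

test_that("polynomial ear axis fits exactly and under jitter", {
  # collinear centers, degree 1: zero residual
  ctr <- cbind(x = seq(0, 100, 10), y = 2 + 0.3 * seq(0, 100, 10))
  ax <- fit_ear_axis(ctr, degree = 1)
  expect_lt(ax$rms, 1e-8)
  # known cubic + jitter sigma = 1 px, degree 3: max deviation <= 2 px
  withr::with_seed(11, {
    u <- seq(-100, 100, length.out = 18)
    truth <- cbind(x = 0.002 * u^2 + 1e-5 * u^3, y = u)   # gentle cubic, near-vertical
    jit <- truth + matrix(rnorm(36, 0, 1), ncol = 2)
  })
  ax3 <- fit_ear_axis(jit, degree = 3)
  uv <- phenokit:::polyaxis_project(ax3, truth)
  pred <- phenokit:::polyaxis_eval(ax3, uv[, 1])
  expect_lte(max(sqrt(rowSums((pred - truth)^2))), 2)
  expect_error(fit_ear_axis(ctr[1:3, ], degree = 3), class = "pheno_insufficient_data")
})

test_that("zhang_suen_thin yields thin, contained, idempotent skeletons", {
  bar <- matrix(0L, 20, 110); bar[8:12, 6:105] <- 1L
  sk <- zhang_suen_thin(bar)
  expect_true(all(sk <= bar))                       # subset of input
  px <- which(sk == 1, arr.ind = TRUE)
  expect_gte(length(unique(px[, 2])), 90)           # spans >= 90 columns
  expect_lte(max(table(px[, 2])), 1)                # 1 px thick
  expect_identical(zhang_suen_thin(sk), sk)         # idempotent
  # single pixel is a fixed point
  one <- matrix(0L, 9, 9); one[5, 5] <- 1L
  expect_identical(zhang_suen_thin(one), one)
  # annulus: topology preserved (one component, one hole)
  h <- 120; ring <- (phenokit:::ellipse_mask(h, h, c(60, 60), 45, 45) &
                     !phenokit:::ellipse_mask(h, h, c(60, 60), 25, 25)) * 1L
  rsk <- zhang_suen_thin(ring)
  expect_equal(label_instances(rsk)$n_instances, 1L)
  # hole count: components of the background under 4-connectivity, minus outer
  bg <- label_instances(1L - rsk, connectivity = 4)
  expect_equal(bg$n_instances, 2L)
})

test_that("angle_at_vertex matches an independent atan2 oracle", {
  expect_equal(angle_at_vertex(c(0, 0), c(1, 0), c(0, 1)), 90)
  expect_equal(angle_at_vertex(c(0, 0), c(1, 0), c(1, 1)), 45)
  withr::with_seed(12, {
    for (i in 1:1000) {
      v <- runif(2, -50, 50); p1 <- runif(2, -50, 50); p2 <- runif(2, -50, 50)
      if (all(p1 == v) || all(p2 == v)) next
      expect_equal(angle_at_vertex(v, p1, p2), angle_atan2_oracle(v, p1, p2),
                   tolerance = 1e-11)
    }
  })
  expect_error(angle_at_vertex(c(0, 0), c(0, 0), c(1, 1)), class = "pheno_degenerate")
})

test_that("flag_leaf_angle implements both modes and needs L", {
  k <- keypoint_triple(A = c(0, -10), B = c(0, 10), C = c(0, 0), L = c(10, 10))
  expect_equal(flag_leaf_angle(k, "node_stem_leaf"), 45)
  k2 <- keypoint_triple(A = c(0, -10), B = c(0, 10), C = c(0, 0), L = c(5, 0))
  expect_equal(flag_leaf_angle(k2, "stem_axis_leaf"), 90)
  # L on the extension of C -> B: zero angle
  k3 <- keypoint_triple(A = c(0, -10), B = c(0, 10), C = c(0, 0), L = c(0, 25))
  expect_equal(flag_leaf_angle(k3, "node_stem_leaf"), 0)
  kL <- keypoint_triple(A = c(0, -10), B = c(0, 10), C = c(0, 0))
  expect_error(flag_leaf_angle(kL), class = "pheno_insufficient_keypoints")
  expect_error(keypoint_triple(A = c(1, 1), B = c(1, 1), C = c(0, 0)),
               class = "pheno_invalid_input")
})

test_that("spikelet angles against straight and curved axes", {
  # straight vertical axis, spikelet parallel -> 0; at 40 degrees -> 40
  ctr <- cbind(x = rep(0, 8), y = seq(0, 140, 20))
  ax <- fit_ear_axis(ctr, degree = 1)
  vert <- structure(list(point = c(0, 50), direction = c(0, 1), inlier_count = 8),
                    class = "pheno_line")
  expect_lt(spikelet_angle(vert, ax, c(0, 50)), 1e-6)
  d40 <- c(sin(40 * pi / 180), cos(40 * pi / 180))
  tilt <- structure(list(point = c(0, 50), direction = d40, inlier_count = 8),
                    class = "pheno_line")
  expect_equal(spikelet_angle(tilt, ax, c(0, 50)), 40, tolerance = 1e-6)
  # out-of-domain center is rejected
  expect_error(spikelet_angle(vert, ax, c(0, 400), domain_tol_px = 10),
               class = "pheno_out_of_domain")
})

test_that("angles are invariant to rotation, translation and scaling of coordinates", {
  withr::with_seed(13, {
    for (i in 1:25) {
      k <- keypoint_triple(A = runif(2, 0, 100), B = runif(2, 0, 100),
                           C = runif(2, 0, 100), L = runif(2, 0, 100))
      base <- flag_leaf_angle(k)
      deg <- runif(1, 0, 360); off <- runif(2, -40, 40); s <- runif(1, 0.5, 3)
      tr <- function(p) as.numeric(s * rotate_pts(matrix(p, 1, 2), deg) + off)
      k2 <- keypoint_triple(tr(k$A), tr(k$B), tr(k$C), tr(k$L))
      expect_equal(flag_leaf_angle(k2), base, tolerance = 1e-6)
    }
  })
  # spikelet_angle under rigid transform of all inputs
  withr::with_seed(14, {
    ctr <- cbind(x = 0.01 * seq(-80, 80, 10)^2, y = seq(-80, 80, 10))
    ax <- fit_ear_axis(ctr, degree = 2)
    sp <- structure(list(point = c(10, 0), direction = phenokit:::normalize_direction(c(0.3, 1)),
                         inlier_count = 10), class = "pheno_line")
    base <- spikelet_angle(sp, ax, c(5, 0))
    for (i in 1:10) {
      deg <- runif(1, 0, 360); off <- runif(2, -30, 30)
      ctr2 <- rotate_pts(ctr, deg) + matrix(off, nrow(ctr), 2, byrow = TRUE)
      ax2 <- fit_ear_axis(ctr2, degree = 2)
      d2 <- as.numeric(rotate_pts(matrix(sp$direction, 1, 2), deg))
      sp2 <- structure(list(point = c(0, 0), direction = phenokit:::normalize_direction(d2),
                            inlier_count = 10), class = "pheno_line")
      c2 <- as.numeric(rotate_pts(matrix(c(5, 0), 1, 2), deg) + off)
      expect_equal(spikelet_angle(sp2, ax2, c2), base, tolerance = 1e-6)
    }
  })
})
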