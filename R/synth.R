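# Synthetic scene generators emulating the recommended capture setups
# (top-down seeds/tomatoes/canopy on black background with a coin for scale,
# side view of a wheat ear, horizontal maize ear, marked field plot), with
# machine-readable ground truth. Rasterization is pixel-center membership
# with no anti-aliasing, so ground-truth masks are exact; additive Gaussian
# noise is applied to background pixels only.

#' @noRd
blank_rgb <- function(h, w) array(0, dim = c(h, w, 3))

# linear pixel indices of an ellipse: center (row, col), semi-axes a >= b
# along direction theta_deg measured in (x = col, y = row) screen coordinates;
# membership is pixel-center-inside, computed on the bounding box only
#' @noRd
ellipse_indices <- function(h, w, center, a, b, theta_deg = 0) {
  th <- theta_deg * pi / 180
  r0 <- max(1L, floor(center[1] - a)); r1 <- min(h, ceiling(center[1] + a))
  c0 <- max(1L, floor(center[2] - a)); c1 <- min(w, ceiling(center[2] + a))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - center[1], length(rr), length(cc))
  dx <- matrix(cc - center[2], length(rr), length(cc), byrow = TRUE)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  sel <- which((u / a)^2 + (v / b)^2 <= 1, arr.ind = TRUE)
  (cc[sel[, 2]] - 1L) * h + rr[sel[, 1]]
}

#' @noRd
ellipse_mask <- function(h, w, center, a, b, theta_deg = 0) {
  m <- matrix(FALSE, h, w)
  m[ellipse_indices(h, w, center, a, b, theta_deg)] <- TRUE
  m
}

# paint color at linear indices of each channel plane of a (h, w, 3) array
#' @noRd
paint_idx <- function(img, idx, color) {
  n <- dim(img)[1] * dim(img)[2]
  img[idx] <- color[1]; img[idx + n] <- color[2]; img[idx + 2 * n] <- color[3]
  img
}

#' @noRd
paint_rgb <- function(img, mask, color) paint_idx(img, which(mask), color)

# batched paint: one assignment per channel for a whole instance list
# (per-call paint_idx would copy the full array once per instance); for
# duplicated indices (overlapping instances) the later instance wins
#' @noRd
paint_multi <- function(img, idx_list, col_list) {
  if (!length(idx_list)) return(img)
  n <- dim(img)[1] * dim(img)[2]
  len <- lengths(idx_list)
  ii <- unlist(idx_list, use.names = FALSE)
  cm <- do.call(rbind, col_list)
  img[ii] <- rep(cm[, 1], len)
  img[ii + n] <- rep(cm[, 2], len)
  img[ii + 2 * n] <- rep(cm[, 3], len)
  img
}

# additive Gaussian noise on background (pixels outside `occupied`)
#' @noRd
add_background_noise <- function(img, occupied, sd) {
  if (sd <= 0) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  nz <- matrix(stats::rnorm(h * w, 0, sd), h, w)
  nz[occupied] <- 0
  for (ch in 1:3) img[, , ch] <- clamp(img[, , ch] + nz, 0, 1)
  img
}

# place n centers in [margin, h-margin] x [margin, w-margin] with pairwise
# center distance >= sep(i, j); radii gives each object's clearance radius
#' @noRd
place_centers <- function(h, w, radii, margin, seed_centers = NULL, max_tries = 4000) {
  centers <- seed_centers
  placed_r <- if (is.null(seed_centers)) numeric(0) else attr(seed_centers, "radii")
  for (r in radii) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- c(stats::runif(1, margin + r, h - margin - r),
             stats::runif(1, margin + r, w - margin - r))
      if (is.null(centers) ||
          all((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 >=
              (placed_r + r + 4)^2)) {
        centers <- rbind(centers, p)
        placed_r <- c(placed_r, r)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      pheno_error("pheno_scene_unrenderable", "could not place all objects; reduce counts or sizes")
  }
  attr(centers, "radii") <- placed_r
  centers
}

#' Generate a synthetic seed-tray scene
#'
#' Ellipse "seeds" scattered on a black background, photographed top-down,
#' optionally with a grey reference coin and with a controlled number of
#' touching seed pairs. Pair overlap is parameterized as
#' `1 - d / (a1 + a2)` where `d` is the center distance along the shared
#' major axis (0 = tangent ellipses).
#'
#' @param n_seeds total number of seeds (touching pairs count as 2).
#' @param n_overlap_pairs number of touching pairs among them.
#' @param overlap pair overlap fraction in `[0, 0.5)`.
#' @param image_size `c(h, w)` pixels.
#' @param coin include a reference coin disc?
#' @param coin_radius_px coin radius in pixels.
#' @param coin_diameter_mm physical coin diameter, fixing the true scale
#'   `mm_per_px = coin_diameter_mm / (2 coin_radius_px)`.
#' @param semi_major,aspect uniform sampling ranges for seed semi-major axis
#'   (px) and elongation (major/minor).
#' @param noise_sd background Gaussian noise sd (image units, default 5/255).
#' @param seed RNG seed; the scene is a pure function of the arguments.
#' @return object of class `"pheno_scene"`: `image` (RGB array), `gt` (list
#'   with per-seed `centers`/`a`/`b`/`theta`, `count`, `coin`, `mm_per_px`,
#'   exact foreground `mask` of the seeds), `kind = "seed_tray"`.
#' @export
gen_seed_tray <- function(n_seeds = 50, n_overlap_pairs = 0, overlap = 0.25,
                          image_size = c(640, 640), coin = TRUE,
                          coin_radius_px = 60, coin_diameter_mm = 25,
                          semi_major = c(8, 14), aspect = c(1.6, 2.4),
                          noise_sd = 5 / 255, seed = 1) {
  stopifnot(n_seeds >= 2 * n_overlap_pairs, overlap >= 0, overlap < 0.5)
  h <- image_size[1]; w <- image_size[2]
  with_local_seed(seed, {
    n_single <- n_seeds - 2L * n_overlap_pairs
    coin_center <- NULL
    anchor <- NULL
    if (coin) {
      coin_center <- c(coin_radius_px + 30 + stats::runif(1, 0, 10),
                       coin_radius_px + 30 + stats::runif(1, 0, 10))
      anchor <- matrix(coin_center, 1, 2)
      attr(anchor, "radii") <- coin_radius_px
    }
    # sample seed geometry
    a_s <- stats::runif(n_single, semi_major[1], semi_major[2])
    th_s <- stats::runif(n_single, 0, 180)
    a_p <- stats::runif(2 * n_overlap_pairs, semi_major[1], semi_major[2])
    th_p <- stats::runif(n_overlap_pairs, 0, 180)
    # placement: singles individually, pairs as one unit with larger clearance
    pair_d <- if (n_overlap_pairs > 0)
      (1 - overlap) * (a_p[seq(1, by = 2, length.out = n_overlap_pairs)] +
                       a_p[seq(2, by = 2, length.out = n_overlap_pairs)])
      else numeric(0)
    unit_r <- c(a_s, if (n_overlap_pairs > 0) pair_d / 2 + pmax(
      a_p[seq(1, by = 2, length.out = n_overlap_pairs)],
      a_p[seq(2, by = 2, length.out = n_overlap_pairs)]))
    centers <- place_centers(h, w, unit_r, margin = 18, seed_centers = anchor)
    if (coin) centers <- centers[-1, , drop = FALSE]
    aspects <- stats::runif(n_seeds, aspect[1], aspect[2])
    # expand pair units into two seed centers along the pair axis
    rows <- list()
    k <- 0
    for (i in seq_len(n_single)) {
      k <- k + 1
      rows[[k]] <- c(centers[i, ], a_s[i], a_s[i] / aspects[k], th_s[i], 0)
    }
    for (p in seq_len(n_overlap_pairs)) {
      # major-axis direction in (drow, dcol): the ellipse is rendered at
      # theta_deg = 90 - theta in (x = col, y = row) coordinates
      u <- c(cos(th_p[p] * pi / 180), sin(th_p[p] * pi / 180))
      ctr <- centers[n_single + p, ]
      for (s in c(-0.5, 0.5)) {
        k <- k + 1
        ai <- a_p[2 * (p - 1) + (s > 0) + 1]
        rows[[k]] <- c(ctr + s * pair_d[p] * u, ai, ai / aspects[k], th_p[p], p)
      }
    }
    gtm <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(0), 0, 6)
    colnames(gtm) <- c("row", "col", "a", "b", "theta", "pair")
    # render
    img <- blank_rgb(h, w)
    seed_mask <- matrix(FALSE, h, w)
    base <- c(0.78, 0.66, 0.45)
    idxs <- vector("list", nrow(gtm)); cols <- vector("list", nrow(gtm))
    for (i in seq_len(nrow(gtm))) {
      idxs[[i]] <- ellipse_indices(h, w, gtm[i, 1:2], gtm[i, "a"], gtm[i, "b"],
                                   theta_deg = 90 - gtm[i, "theta"])
      cols[[i]] <- clamp(base + stats::runif(1, -0.06, 0.06), 0, 1)
      seed_mask[idxs[[i]]] <- TRUE
    }
    img <- paint_multi(img, idxs, cols)
    occupied <- seed_mask
    coin_gt <- NULL
    if (coin) {
      cm <- ellipse_mask(h, w, coin_center, coin_radius_px, coin_radius_px)
      img <- paint_rgb(img, cm, c(0.62, 0.62, 0.62))
      occupied <- occupied | cm
      coin_gt <- list(center = coin_center, radius = coin_radius_px,
                      diameter_mm = coin_diameter_mm)
    }
    img <- add_background_noise(img, occupied, noise_sd)
    structure(list(
      image = img,
      gt = list(seeds = as.data.frame(gtm), count = nrow(gtm), coin = coin_gt,
                mm_per_px = if (coin) coin_diameter_mm / (2 * coin_radius_px) else NA_real_,
                mask = seed_mask * 1L),
      kind = "seed_tray", seed = seed
    ), class = "pheno_scene")
  })
}

#' Generate a synthetic tomato scene
#'
#' Red discs with hue jitter on a dark background, optionally with a grey
#' reference coin.
#'
#' @param n_tomatoes number of fruits.
#' @param radius_range uniform sampling range of disc radii (px).
#' @param hue_jitter_deg hue jitter around 0 degrees (red), +/- degrees.
#' @inheritParams gen_seed_tray
#' @return a `"pheno_scene"` with `gt$tomatoes` (centers, radii), `gt$count`,
#'   `gt$coin`, `gt$mm_per_px`, exact `gt$mask`.
#' @export
gen_tomato_scene <- function(n_tomatoes = 8, radius_range = c(25, 45),
                             image_size = c(640, 640), coin = TRUE,
                             coin_radius_px = 60, coin_diameter_mm = 25,
                             hue_jitter_deg = 10, noise_sd = 5 / 255, seed = 1) {
  h <- image_size[1]; w <- image_size[2]
  with_local_seed(seed, {
    coin_center <- NULL; anchor <- NULL
    if (coin) {
      coin_center <- c(coin_radius_px + 30, coin_radius_px + 30)
      anchor <- matrix(coin_center, 1, 2)
      attr(anchor, "radii") <- coin_radius_px
    }
    radii <- if (n_tomatoes > 0) stats::runif(n_tomatoes, radius_range[1], radius_range[2]) else numeric(0)
    centers <- place_centers(h, w, radii, margin = 15, seed_centers = anchor)
    if (coin) centers <- centers[-1, , drop = FALSE]
    img <- blank_rgb(h, w)
    tm <- matrix(FALSE, h, w)
    hues <- if (n_tomatoes > 0) (stats::runif(n_tomatoes, -hue_jitter_deg, hue_jitter_deg) + 360) %% 360 else numeric(0)
    idxs <- vector("list", n_tomatoes); cols <- vector("list", n_tomatoes)
    for (i in seq_len(n_tomatoes)) {
      idxs[[i]] <- ellipse_indices(h, w, centers[i, ], radii[i], radii[i])
      cols[[i]] <- as.numeric(grDevices::col2rgb(grDevices::hsv(hues[i] / 360, 0.85, 0.8))) / 255
      tm[idxs[[i]]] <- TRUE
    }
    img <- paint_multi(img, idxs, cols)
    occupied <- tm
    coin_gt <- NULL
    if (coin) {
      cm <- ellipse_mask(h, w, coin_center, coin_radius_px, coin_radius_px)
      img <- paint_rgb(img, cm, c(0.62, 0.62, 0.62))
      occupied <- occupied | cm
      coin_gt <- list(center = coin_center, radius = coin_radius_px,
                      diameter_mm = coin_diameter_mm)
    }
    img <- add_background_noise(img, occupied, noise_sd)
    structure(list(
      image = img,
      gt = list(
        tomatoes = if (n_tomatoes > 0)
          data.frame(row = centers[, 1], col = centers[, 2], radius = radii, hue = hues)
        else data.frame(row = numeric(0), col = numeric(0), radius = numeric(0), hue = numeric(0)),
        count = n_tomatoes, coin = coin_gt,
        mm_per_px = if (coin) coin_diameter_mm / (2 * coin_radius_px) else NA_real_,
        mask = tm * 1L
      ),
      kind = "tomato", seed = seed
    ), class = "pheno_scene")
  })
}

#' Generate a synthetic wheat-ear spikelet scene
#'
#' Ellipse spikelets placed alternately left/right along a polynomial
#' (default cubic) ear axis, each tilted by a fixed angle to the local axis
#' tangent — the generative model behind spikelet counting and angle
#' recovery. Optional Gaussian jitter perturbs the centers.
#'
#' @param n_spikelets number of spikelets.
#' @param angle_deg fixed spikelet-to-tangent angle (degrees).
#' @param axis_coeffs cubic coefficients `c(c1, c2, c3)` of the axis lateral
#'   displacement `x(t) = c1 t + c2 t^2 + c3 t^3` for normalized `t` in
#'   `[-1, 1]` along the ear; `NULL` for the default gentle curve.
#' @param image_size `c(h, w)` pixels.
#' @param spikelet_a,spikelet_b spikelet ellipse semi-axes (px).
#' @param lateral_offset center offset from the axis (px).
#' @param center_jitter_sd Gaussian sd (px) added to spikelet centers.
#' @param noise_sd background noise sd.
#' @param seed RNG seed.
#' @return a `"pheno_scene"` with `gt` holding `centers` (n x 2 row/col),
#'   `angle_deg`, `axis` (function of t and sampled points), `count`, exact
#'   `mask`.
#' @export
gen_spikelet_ear <- function(n_spikelets = 18, angle_deg = 35, axis_coeffs = NULL,
                             image_size = c(520, 340), spikelet_a = 19,
                             spikelet_b = 7, lateral_offset = 14,
                             center_jitter_sd = 0, noise_sd = 5 / 255, seed = 1) {
  h <- image_size[1]; w <- image_size[2]
  if (is.null(axis_coeffs)) axis_coeffs <- c(12, 20, -14)
  with_local_seed(seed, {
    margin <- 45
    t <- seq(-1, 1, length.out = n_spikelets)
    yy <- margin + (t + 1) / 2 * (h - 2 * margin)
    xx <- w / 2 + axis_coeffs[1] * t + axis_coeffs[2] * t^2 + axis_coeffs[3] * t^3
    # tangent d(col)/d(row): dx/dt / dy/dt
    dxdt <- axis_coeffs[1] + 2 * axis_coeffs[2] * t + 3 * axis_coeffs[3] * t^2
    dydt <- (h - 2 * margin) / 2
    tang <- cbind(dxdt, dydt)                 # (dcol, drow), unnormalized
    tang <- tang / sqrt(rowSums(tang^2))
    nrm <- cbind(tang[, 2], -tang[, 1])       # normal (dcol, drow)
    side <- rep(c(-1, 1), length.out = n_spikelets)
    ctr_col <- xx + side * lateral_offset * nrm[, 1]
    ctr_row <- yy + side * lateral_offset * nrm[, 2]
    if (center_jitter_sd > 0) {
      ctr_col <- ctr_col + stats::rnorm(n_spikelets, 0, center_jitter_sd)
      ctr_row <- ctr_row + stats::rnorm(n_spikelets, 0, center_jitter_sd)
    }
    # spikelet major axis: tangent rotated outward by angle_deg
    tang_ang <- atan2(tang[, 2], tang[, 1]) * 180 / pi   # in (x=col, y=row)
    maj_ang <- tang_ang + side * angle_deg
    img <- blank_rgb(h, w)
    sm <- matrix(FALSE, h, w)
    base <- c(0.84, 0.74, 0.44)
    idxs <- vector("list", n_spikelets); cols <- vector("list", n_spikelets)
    for (i in seq_len(n_spikelets)) {
      idxs[[i]] <- ellipse_indices(h, w, c(ctr_row[i], ctr_col[i]), spikelet_a, spikelet_b,
                                   theta_deg = maj_ang[i])
      cols[[i]] <- clamp(base + stats::runif(1, -0.05, 0.05), 0, 1)
      sm[idxs[[i]]] <- TRUE
    }
    img <- paint_multi(img, idxs, cols)
    img <- add_background_noise(img, sm, noise_sd)
    structure(list(
      image = img,
      gt = list(
        centers = cbind(row = ctr_row, col = ctr_col),
        axis_points = cbind(row = yy, col = xx),
        tangent_angle_deg = tang_ang,
        angle_deg = angle_deg, count = n_spikelets,
        axis_coeffs = axis_coeffs, mask = sm * 1L
      ),
      kind = "spikelet_ear", seed = seed
    ), class = "pheno_scene")
  })
}

#' Generate a maize kernel lattice
#'
#' Kernel centroids on a rows-by-columns lattice (ear long axis along x),
#' with Gaussian jitter and a global rotation; optionally rendered as yellow
#' blobs on a dark background.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param pitch_row,pitch_col lattice pitch (px) across / along the ear.
#' @param jitter_frac jitter sd as a fraction of the respective pitch.
#' @param rotation_deg global rotation applied to the lattice.
#' @param render if `TRUE`, also render an image of yellow kernel discs.
#' @param kernel_radius disc radius for rendering.
#' @param seed RNG seed.
#' @return a `"pheno_scene"` with `gt` holding `points` (n x 2 `(x, y)`),
#'   `row_label`, `n_rows`, `n_cols`, `rotation_deg`; `image` is `NULL`
#'   unless rendered.
#' @export
gen_corn_lattice <- function(n_rows = 14, n_cols = 30, pitch_row = 20,
                             pitch_col = 16, jitter_frac = 0.1,
                             rotation_deg = 0, render = FALSE,
                             kernel_radius = 4, seed = 1) {
  with_local_seed(seed, {
    grid <- expand.grid(r = seq_len(n_rows), c = seq_len(n_cols))
    x <- grid$c * pitch_col + stats::rnorm(nrow(grid), 0, jitter_frac * pitch_col)
    y <- grid$r * pitch_row + stats::rnorm(nrow(grid), 0, jitter_frac * pitch_row)
    a <- rotation_deg * pi / 180
    pts <- cbind(x = x * cos(a) - y * sin(a), y = x * sin(a) + y * cos(a))
    img <- NULL
    if (render) {
      pad <- 3 * kernel_radius
      pts_r <- sweep(pts, 2, apply(pts, 2, min)) + pad
      h <- ceiling(max(pts_r[, 2]) + pad); w <- ceiling(max(pts_r[, 1]) + pad)
      img <- blank_rgb(h, w)
      occ <- matrix(FALSE, h, w)
      idxs <- vector("list", nrow(pts_r))
      for (i in seq_len(nrow(pts_r))) {
        idxs[[i]] <- ellipse_indices(h, w, c(pts_r[i, 2], pts_r[i, 1]), kernel_radius, kernel_radius)
        occ[idxs[[i]]] <- TRUE
      }
      img <- paint_multi(img, idxs, rep(list(c(0.9, 0.78, 0.18)), nrow(pts_r)))
      img <- add_background_noise(img, occ, 5 / 255)
      pts <- pts_r
    }
    structure(list(
      image = img,
      gt = list(points = pts, row_label = grid$r, n_rows = n_rows,
                n_cols = n_cols, rotation_deg = rotation_deg,
                pitch_row = pitch_row, pitch_col = pitch_col),
      kind = "corn_lattice", seed = seed
    ), class = "pheno_scene")
  })
}

#' Generate a synthetic canopy scene
#'
#' A canopy silhouette (disc or star) textured green/brown at an exact pixel
#' fraction on a dark background. The star silhouette has the same analytic
#' area as the disc of the same nominal radius, so shapes differ while area
#' is held fixed.
#'
#' @param kind `"disc"` or `"star"`.
#' @param radius nominal silhouette radius (px).
#' @param green_fraction exact fraction of silhouette pixels textured green.
#' @param image_size `c(h, w)`.
#' @param n_arms number of star arms.
#' @param noise_sd background noise sd.
#' @param seed RNG seed.
#' @return a `"pheno_scene"` with `gt` holding the exact `mask`, `area_px`,
#'   `green_fraction` (realized, after pixel rounding), `kind`.
#' @export
gen_canopy <- function(kind = c("disc", "star"), radius = 150,
                       green_fraction = 0.7, image_size = c(520, 520),
                       n_arms = 7, noise_sd = 5 / 255, seed = 1) {
  kind <- match.arg(kind)
  h <- image_size[1]; w <- image_size[2]
  with_local_seed(seed, {
    ctr <- c(h / 2, w / 2)
    rr <- matrix(seq_len(h) - ctr[1], h, w)
    cc <- matrix(seq_len(w) - ctr[2], h, w, byrow = TRUE)
    rho <- sqrt(rr^2 + cc^2)
    if (kind == "disc") {
      mask <- rho <= radius
    } else {
      phi <- atan2(rr, cc)
      scale <- 1 / sqrt(0.55^2 + 0.45^2 / 2)   # equal analytic area to the disc
      rphi <- radius * scale * (0.55 + 0.45 * cos(n_arms * phi))
      mask <- rho <= rphi
    }
    n <- sum(mask)
    n_green <- round(green_fraction * n)
    idx <- which(mask)
    green_idx <- sample(idx, n_green)
    img <- blank_rgb(h, w)
    img <- paint_rgb(img, mask, c(0.45, 0.33, 0.18))       # brown base
    gm <- matrix(FALSE, h, w); gm[green_idx] <- TRUE
    img <- paint_rgb(img, gm, c(0.20, 0.55, 0.22))
    img <- add_background_noise(img, mask, noise_sd)
    structure(list(
      image = img,
      gt = list(mask = mask * 1L, area_px = n,
                green_fraction = n_green / n, shape = kind, radius = radius),
      kind = "canopy", seed = seed
    ), class = "pheno_scene")
  })
}

#' Generate a synthetic marked wheat plot
#'
#' A white rectangular marker frame of known physical size drawn on a dark
#' vegetation background under a known projective warp, with bright
#' head-like blobs at an exact count inside the marker (plus optional
#' distractor heads outside). The ground-truth homography maps world
#' millimetre coordinates to image pixels.
#'
#' @param density_per_m2 head count per square metre inside the marker
#'   (rounded to an integer count).
#' @param marker_w_m,marker_h_m marker outer dimensions (metres).
#' @param frame_mm frame stroke width (mm).
#' @param head_radius_mm head blob radius (mm).
#' @param n_outside distractor heads outside the marker.
#' @param px_per_mm nominal image scale of the warp.
#' @param rotation_deg in-plane rotation of the warp.
#' @param perspective length-2 projective coefficients of the warp (small,
#'   e.g. `c(5e-5, -4e-5)`); `c(0, 0)` for an affine view.
#' @param image_size `c(h, w)`.
#' @param noise_sd background noise sd.
#' @param seed RNG seed.
#' @return a `"pheno_scene"` with `gt` holding `H` (world (x, y) mm -> image
#'   (x, y) px), marker `corners_world` / `corners_image` (outer), head
#'   centers, `n_inside`, `density_per_m2`.
#' @export
gen_wheat_plot <- function(density_per_m2 = 60, marker_w_m = 1, marker_h_m = 1,
                           frame_mm = 30, head_radius_mm = 28, n_outside = 5,
                           px_per_mm = 0.42, rotation_deg = 0,
                           perspective = c(0, 0), image_size = c(560, 560),
                           noise_sd = 4 / 255, seed = 1) {
  h <- image_size[1]; w <- image_size[2]
  wm <- marker_w_m * 1000; hm <- marker_h_m * 1000
  with_local_seed(seed, {
    n_in <- round(density_per_m2 * marker_w_m * marker_h_m)
    # head placement in world mm, inside the inner frame area
    pad <- frame_mm + head_radius_mm + 5
    inner <- c(pad, wm - pad, pad, hm - pad)
    pts <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n_in)) {
      for (t in 1:4000) {
        p <- c(stats::runif(1, inner[1], inner[2]), stats::runif(1, inner[3], inner[4]))
        if (nrow(pts) == 0 ||
            min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= (2 * head_radius_mm + 12)^2) {
          pts <- rbind(pts, p); break
        }
      }
    }
    if (nrow(pts) < n_in)
      pheno_error("pheno_scene_unrenderable", "could not place heads at requested density")
    out_pts <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n_outside)) {
      p <- c(stats::runif(1, -0.25 * wm, 1.25 * wm), stats::runif(1, -0.25 * hm, 1.25 * hm))
      if (p[1] < -2 * head_radius_mm || p[1] > wm + 2 * head_radius_mm ||
          p[2] < -2 * head_radius_mm || p[2] > hm + 2 * head_radius_mm)
        out_pts <- rbind(out_pts, p)
    }
    # world -> image homography: center the marker in the image
    a <- rotation_deg * pi / 180
    S <- matrix(c(px_per_mm * cos(a), -px_per_mm * sin(a), 0,
                  px_per_mm * sin(a),  px_per_mm * cos(a), 0,
                  perspective[1], perspective[2], 1), 3, 3, byrow = TRUE)
    ctr_w <- apply_homography(S, matrix(c(wm / 2, hm / 2), 1, 2))
    S[1, 3] <- w / 2 - ctr_w[1, 1]
    S[2, 3] <- h / 2 - ctr_w[1, 2]
    H <- S / S[3, 3]
    # render by inverse mapping: world coords of every pixel
    Hi <- solve(H)
    xy <- cbind(rep(seq_len(w), each = h), rep(seq_len(h), times = w))
    wc <- apply_homography(Hi, xy)
    wx <- wc[, 1]; wy <- wc[, 2]
    in_outer <- wx >= 0 & wx <= wm & wy >= 0 & wy <= hm
    in_inner <- wx >= frame_mm & wx <= wm - frame_mm & wy >= frame_mm & wy <= hm - frame_mm
    frame <- in_outer & !in_inner
    head_m <- rep(FALSE, length(wx))
    allheads <- rbind(pts, out_pts)
    for (i in seq_len(nrow(allheads)))
      head_m <- head_m | ((wx - allheads[i, 1])^2 + (wy - allheads[i, 2])^2 <= head_radius_mm^2)
    head_m <- head_m & !frame
    img <- blank_rgb(h, w)
    bg_col <- c(0.07, 0.12, 0.05)
    for (ch in 1:3) img[, , ch] <- bg_col[ch]
    fm <- matrix(FALSE, h, w); fm[cbind(xy[, 2], xy[, 1])] <- frame
    hm2 <- matrix(FALSE, h, w); hm2[cbind(xy[, 2], xy[, 1])] <- head_m
    img <- paint_rgb(img, fm, c(1, 1, 1))
    img <- paint_rgb(img, hm2, c(0.80, 0.70, 0.42))
    img <- add_background_noise(img, fm | hm2, noise_sd)
    corners_world <- rbind(c(0, 0), c(wm, 0), c(wm, hm), c(0, hm))
    structure(list(
      image = img,
      gt = list(
        H = H,
        corners_world = corners_world,
        corners_image = apply_homography(H, corners_world),
        heads_world = pts, heads_outside_world = out_pts,
        heads_image = apply_homography(H, pts),
        n_inside = nrow(pts),
        density_per_m2 = nrow(pts) / (marker_w_m * marker_h_m),
        marker_w_m = marker_w_m, marker_h_m = marker_h_m,
        px_per_mm = px_per_mm
      ),
      kind = "wheat_plot", seed = seed
    ), class = "pheno_scene")
  })
}
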