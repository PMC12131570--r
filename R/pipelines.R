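# The seven trait pipelines behind a uniform run interface. Each pipeline is
# deterministic given (image, config, seed); detection stages are pluggable
# backends (classical reference implementations by default) so that any
# external detector producing boxes/points/masks can stand in.

#' Pipeline configuration
#'
#' Merges user settings over the documented defaults. Keys cover calibration
#' (`coin_diameter_mm`, `min_coin_radius_px`, `circularity_min`,
#' `marker_width_m`, `marker_height_m`, `whiteness_threshold`,
#' `marker_angle_tol_deg`), segmentation (`connectivity`,
#' `solidity_threshold`, `peak_min_distance`, `min_area_px`,
#' `opening_radius`, `invert`, `hsv_lower`, `hsv_upper`, `green_lower`,
#' `green_upper`), geometry (`axis_degree`, `ransac_iterations`,
#' `ransac_tol_px`, `leaf_angle_mode`), row features (`k_min`, `k_max`,
#' `n_init`, `row_multiplier`), yield (`head_weight_g`, `yield_area_m2`),
#' and `seed`.
#'
#' @param ... named overrides of the defaults.
#' @return named list of class `"pheno_config"`.
#' @export
pheno_config <- function(...) {
  cfg <- list(
    coin_diameter_mm = 25, min_coin_radius_px = 20, circularity_min = 0.85,
    marker_width_m = 1, marker_height_m = 1,
    whiteness_threshold = 200, marker_angle_tol_deg = 15,
    connectivity = 8, solidity_threshold = 0.985, peak_min_distance = 8,
    min_area_px = 25, opening_radius = 0, invert = FALSE,
    hsv_lower = c(340, 0.3, 0.2), hsv_upper = c(20, 1, 1),       # red band
    green_lower = c(60, 0.15, 0.1), green_upper = c(180, 1, 1),  # green band
    axis_degree = 3, ransac_iterations = 200, ransac_tol_px = 2,
    leaf_angle_mode = "node_stem_leaf",
    k_min = 4, k_max = 24, n_init = 10, row_multiplier = 1,
    head_weight_g = NULL,
    seed = 1
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    pheno_error("pheno_invalid_parameter", paste("unknown config keys:", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "pheno_config")
}

#' @noRd
as_pheno_config <- function(config) {
  if (inherits(config, "pheno_config")) config
  else if (is.null(config)) pheno_config()
  else do.call(pheno_config, as.list(config))
}

#' @noRd
provenance_block <- function(pipeline, config, backend = "classical") {
  list(pipeline = pipeline, version = as.character(utils::packageVersion("phenokit")),
       seed = config$seed, config_hash = fnv1a32(unclass(config)), backend = backend)
}

#' @noRd
pheno_result <- function(pipeline, calibration, traits, config,
                         backend = "classical", records = NULL, extra = list()) {
  structure(c(list(
    pipeline = pipeline, calibration = calibration, traits = traits,
    records = records, provenance = provenance_block(pipeline, config, backend)
  ), extra), class = "pheno_result")
}

#' @export
print.pheno_result <- function(x, ...) {
  cat("<pheno_result> pipeline:", x$pipeline, "\n")
  print(x$calibration)
  if (inherits(x$traits, "pheno_summary") || inherits(x$traits, "pheno_rowfeatures"))
    print(x$traits)
  else utils::str(x$traits, max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Serialize a pipeline result to JSON
#'
#' @param result a `"pheno_result"`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
result_to_json <- function(result, path = NULL) {
  x <- unclass(result)
  x$calibration <- unclass(x$calibration)
  if (inherits(x$traits, "pheno_summary") || inherits(x$traits, "pheno_rowfeatures"))
    x$traits <- unclass(x$traits)
  if (!is.null(x$traits$calibration)) x$traits$calibration <- unclass(x$traits$calibration)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# mask of the detected coin dilated by `pad` pixels, for exclusion
#' @noRd
coin_exclusion_mask <- function(dimhw, coin, pad = 2) {
  ellipse_mask(dimhw[1], dimhw[2], coin$center, coin$radius + pad, coin$radius + pad)
}

# shared coin stage: returns list(cal, coin or NULL)
#' @noRd
coin_stage <- function(img, config) {
  coin <- tryCatch(
    detect_coin(img, min_radius_px = config$min_coin_radius_px,
                circularity_min = config$circularity_min),
    phenoError = function(e) NULL
  )
  if (is.null(coin)) list(cal = calibration(), coin = NULL)
  else list(cal = scale_from_coin(coin, config$coin_diameter_mm), coin = coin)
}

#' Seed morphometrics pipeline
#'
#' Coin detection establishes the scale factor (optional; absent coin means
#' pixel units), Otsu thresholding of the luminance channel segments the
#' seeds (excluding the coin region, dilated 2 px), the mask is cleaned,
#' labeled, touching seeds are split, and per-seed morphometrics plus a
#' scene summary are reported.
#'
#' @param img RGB array `[h, w, 3]` in `[0,1]`, or a PNG path.
#' @param config a [pheno_config()] or named list of overrides.
#' @return a `"pheno_result"` with `traits` (a `"pheno_summary"`), `records`
#'   (per-seed trait table) and `labelmap`.
#' @export
run_seed_pheno <- function(img, config = pheno_config()) {
  config <- as_pheno_config(config)
  if (is.character(img)) img <- read_image_rgb(img)
  cs <- coin_stage(img, config)
  gray <- luminance(img)
  t <- otsu_threshold(gray_histogram(gray))
  mask <- if (config$invert) (gray <= t) * 1L else (gray > t) * 1L
  if (!is.null(cs$coin)) mask[coin_exclusion_mask(dim(gray), cs$coin)] <- 0L
  mask <- clean_mask(mask, config$min_area_px, config$opening_radius)
  lm <- label_instances(mask, config$connectivity)
  lm <- split_adhesions(lm, config$solidity_threshold, config$peak_min_distance)
  rec <- measure_all(lm, cs$cal)
  pheno_result("seed_pheno", cs$cal, summarize_scene(rec, cs$cal), config,
               records = rec, extra = list(labelmap = lm, otsu_level = t))
}

#' Tomato fruit pipeline
#'
#' Bounded-HSV segmentation in the red band (wrapped hue), mask cleanup,
#' instance labeling and adhesion splitting, per-fruit morphometrics. The
#' coin contour check runs on the image with fruit pixels suppressed so the
#' red fruits cannot masquerade as the grey coin. Fruit "diameter" is the
#' equivalent diameter; "width" the rotated-rectangle width.
#'
#' @inheritParams run_seed_pheno
#' @return a `"pheno_result"`; `records` carry per-fruit traits.
#' @export
run_tomato_pheno <- function(img, config = pheno_config()) {
  config <- as_pheno_config(config)
  if (is.character(img)) img <- read_image_rgb(img)
  mask <- hsv_in_range(img, hsv_bounds(config$hsv_lower, config$hsv_upper))
  img_nored <- img
  for (ch in 1:3) { pl <- img_nored[, , ch]; pl[mask > 0] <- 0; img_nored[, , ch] <- pl }
  cs <- coin_stage(img_nored, config)
  if (!is.null(cs$coin)) mask[coin_exclusion_mask(dim(mask), cs$coin)] <- 0L
  mask <- clean_mask(mask, config$min_area_px, config$opening_radius)
  lm <- label_instances(mask, config$connectivity)
  lm <- split_adhesions(lm, config$solidity_threshold, config$peak_min_distance)
  rec <- measure_all(lm, cs$cal)
  pheno_result("tomato_pheno", cs$cal, summarize_scene(rec, cs$cal), config,
               records = rec, extra = list(labelmap = lm))
}

#' Spikelet counting and morphology pipeline
#'
#' Otsu segmentation of the ear, adhesion splitting, per-spikelet RANSAC
#' major axes, axis midpoints as center points, polynomial regression of the
#' ear axis through the centers, the Zhang-Suen skeleton of the spikelet
#' distribution, and per-spikelet angles to the local ear-axis tangent. With
#' fewer than `axis_degree + 1` spikelets the ear axis (and angles) are
#' omitted while the count is still reported.
#'
#' @inheritParams run_seed_pheno
#' @return a `"pheno_result"` with `traits` list: `count`, `angles_deg`,
#'   `median_angle_deg`, `ear_axis` (a `"pheno_polyaxis"` or `NULL`);
#'   `extra` carries the skeleton and per-spikelet axes.
#' @export
run_spikelet_pheno <- function(img, config = pheno_config()) {
  config <- as_pheno_config(config)
  if (is.character(img)) img <- read_image_rgb(img)
  gray <- luminance(img)
  t <- otsu_threshold(gray_histogram(gray))
  mask <- if (config$invert) (gray <= t) * 1L else (gray > t) * 1L
  mask <- clean_mask(mask, config$min_area_px, config$opening_radius)
  lm <- label_instances(mask, config$connectivity)
  lm <- split_adhesions(lm, config$solidity_threshold, config$peak_min_distance)
  n <- lm$n_instances
  axes <- vector("list", n)
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    px <- which(lm$labels == i, arr.ind = TRUE)
    pts <- cbind(x = px[, 2], y = px[, 1])
    ax <- ransac_major_axis(pts, config$ransac_iterations, config$ransac_tol_px,
                            seed = config$seed + i)
    # midpoint of the axis segment spanned by the instance
    proj <- (pts[, 1] - ax$point[1]) * ax$direction[1] +
            (pts[, 2] - ax$point[2]) * ax$direction[2]
    mid <- ax$point + mean(range(proj)) * ax$direction
    axes[[i]] <- ax
    centers[i, ] <- mid
  }
  ear <- NULL
  angles <- NULL
  if (n >= config$axis_degree + 1) {
    # Spikelets alternate sides of the rachis, so their midpoints zigzag
    # about the true axis; midpoints of CONSECUTIVE centers (ordered along
    # the ear's principal direction) cancel the alternation and fall on the
    # axis. Fit to those when there are enough; else fit the raw centers.
    axis_pts <- centers
    if (n >= config$axis_degree + 2) {
      pc <- stats::prcomp(centers)$x[, 1]
      ord <- order(pc)
      axis_pts <- (centers[ord[-1], , drop = FALSE] +
                   centers[ord[-n], , drop = FALSE]) / 2
    }
    ear <- fit_ear_axis(axis_pts, config$axis_degree)
    angles <- vapply(seq_len(n), function(i)
      spikelet_angle(axes[[i]], ear, centers[i, ],
                     domain_tol_px = 0.1 * diff(ear$domain) + 5), numeric(1))
  }
  skel <- zhang_suen_thin(mask)
  traits <- list(count = n, angles_deg = angles,
                 median_angle_deg = if (is.null(angles)) NULL else stats::median(angles),
                 ear_axis = ear)
  pheno_result("spikelet_pheno", calibration(), traits, config,
               extra = list(labelmap = lm, spikelet_axes = axes,
                            centers = centers, skeleton = skel))
}

#' Canopy shape and color pipeline
#'
#' The canopy mask is the union of the green HSV band and the Otsu foreground
#' (dark-background capture); the largest connected component is the canopy
#' region, measured for length, width, area, compactness and green ratio.
#'
#' @inheritParams run_seed_pheno
#' @return a `"pheno_result"` with `traits` list: `area_px2`, `length_px`,
#'   `width_px`, `compactness`, `green_ratio`, `count` (0 for an empty
#'   scene).
#' @export
run_canopy_pheno <- function(img, config = pheno_config()) {
  config <- as_pheno_config(config)
  if (is.character(img)) img <- read_image_rgb(img)
  green <- hsv_in_range(img, hsv_bounds(config$green_lower, config$green_upper))
  gray <- luminance(img)
  t <- otsu_threshold(gray_histogram(gray))
  mask <- clean_mask((green > 0 | gray > t) * 1L, config$min_area_px, config$opening_radius)
  lm <- label_instances(mask, config$connectivity)
  if (lm$n_instances == 0) {
    traits <- list(count = 0L, area_px2 = 0, length_px = 0, width_px = 0,
                   compactness = NA_real_, green_ratio = NA_real_)
    return(pheno_result("canopy_pheno", calibration(), traits, config))
  }
  sizes <- vapply(seq_len(lm$n_instances), function(i) sum(lm$labels == i), numeric(1))
  big <- which.max(sizes)
  rec <- measure_instance(lm, big)
  canopy_mask <- (lm$labels == big) * 1L
  gr <- green_ratio(img, canopy_mask, hsv_bounds(config$green_lower, config$green_upper))
  traits <- list(count = 1L, area_px2 = rec$area_px2, length_px = rec$length_px,
                 width_px = rec$width_px, compactness = rec$compactness,
                 green_ratio = gr)
  pheno_result("canopy_pheno", calibration(), traits, config,
               records = rec, extra = list(labelmap = lm, canopy_label = big))
}

# classical blob-centroid backend: threshold an HSV band, label, centroids
#' @noRd
detect_blob_points <- function(img, bounds, min_area_px = 9, connectivity = 8) {
  mask <- hsv_in_range(img, bounds)
  mask <- clean_mask(mask, min_area_px, 0)
  lm <- label_instances(mask, connectivity)
  if (lm$n_instances == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  t(vapply(seq_len(lm$n_instances), function(i) {
    px <- which(lm$labels == i, arr.ind = TRUE)
    c(x = mean(px[, 2]), y = mean(px[, 1]))
  }, numeric(2)))
}

#' Maize kernel row-feature pipeline
#'
#' Kernel centroids come from a CSV file (`x,y` header), an n x 2 matrix, or
#' classical blob detection on a rendered ear image (high-saturation yellow
#' band). The centroids are PCA-aligned so the ear's long axis is horizontal,
#' rows are found by 1-D K-means on the cross-axis coordinate with
#' silhouette model selection over `[k_min, k_max]`, and kernel counts per
#' row are reported. Only the visible face is counted; `row_multiplier`
#' (default 1) scales the row count if a whole-ear convention is wanted.
#'
#' @param x kernel points (matrix/data.frame with columns x, y, or CSV path)
#'   or an RGB image array.
#' @param config a [pheno_config()] or named list of overrides.
#' @return a `"pheno_result"` with `traits` a `"pheno_rowfeatures"` plus the
#'   chosen `k`, silhouette, and alignment angle in `extra`.
#' @export
run_corn_pheno <- function(x, config = pheno_config()) {
  config <- as_pheno_config(config)
  backend <- "points_file"
  if (is.character(x)) {
    pts <- as.matrix(utils::read.csv(x)[, c("x", "y")])
  } else if (is.array(x) && length(dim(x)) == 3) {
    pts <- detect_blob_points(x, hsv_bounds(c(30, 0.35, 0.3), c(70, 1, 1)),
                              min_area_px = config$min_area_px)
    backend <- "classical_blob"
  } else {
    pts <- as.matrix(x)[, 1:2, drop = FALSE]
    backend <- "points"
  }
  if (nrow(pts) < 2)
    pheno_error("pheno_invalid_input", "need at least 2 kernel points")
  al <- pca_align(pts)
  k_max <- min(config$k_max, nrow(pts))
  cl <- cluster_rows(al$points, k_min = min(config$k_min, k_max), k_max = k_max,
                     seed = config$seed, n_init = config$n_init)
  rf <- extract_row_features(cl$assignments, al$points)
  if (config$row_multiplier != 1)
    rf$whole_ear_row_estimate <- rf$visible_row_count * config$row_multiplier
  pheno_result("corn_pheno", calibration(), rf, config, backend = backend,
               extra = list(k = cl$k, silhouette = cl$silhouette,
                            alignment_angle_deg = al$angle_deg,
                            assignments = cl$assignments, points = al$points))
}

#' Flag-leaf angle pipeline
#'
#' Keypoints arrive as a data.frame/CSV with columns `x, y, role` (roles
#' `A` stem base, `B` spike tip, `C` leaf node, `L` leaf reference) or as a
#' [keypoint_triple()]. The angle is computed in the configured mode.
#'
#' @param x keypoints (`"pheno_keypoints"`, data.frame, or CSV path).
#' @param config a [pheno_config()] or named list of overrides.
#' @return a `"pheno_result"` with `traits` list: `angle_deg`, `mode`.
#' @export
run_leaf_angle <- function(x, config = pheno_config()) {
  config <- as_pheno_config(config)
  if (is.character(x)) x <- utils::read.csv(x)
  if (is.data.frame(x)) {
    need <- c("A", "B", "C")
    if (!all(need %in% x$role))
      pheno_error("pheno_insufficient_keypoints", "roles A, B, C are required")
    getp <- function(r) as.numeric(x[match(r, x$role), c("x", "y")])
    x <- keypoint_triple(getp("A"), getp("B"), getp("C"),
                         L = if ("L" %in% x$role) getp("L") else NULL)
  }
  ang <- flag_leaf_angle(x, mode = config$leaf_angle_mode)
  pheno_result("leaf_angle_pheno", calibration(),
               list(angle_deg = ang, mode = config$leaf_angle_mode), config,
               backend = "keypoints")
}

#' Wheat head counting and density pipeline
#'
#' Detects the white rectangular marker, verifies and rectifies it (deriving
#' the scale), finds head-like bright blobs inside the rectified marker
#' interior by Otsu thresholding of the non-white pixels, and reports count,
#' per-head length/width, density (heads per square metre of marker area)
#' and, only when `head_weight_g` is configured, a yield estimate in kg/ha
#' (`density x head weight x 10`). Without a marker the counts are reported
#' uncalibrated and density/yield are omitted.
#'
#' @inheritParams run_seed_pheno
#' @return a `"pheno_result"` with `traits` list: `count`,
#'   `density_per_m2`, `mean_head_length_mm` / `_width_mm` (when
#'   calibrated), `yield_kg_per_ha` (when configured).
#' @export
run_wheat_head <- function(img, config = pheno_config()) {
  config <- as_pheno_config(config)
  if (is.character(img)) img <- read_image_rgb(img)
  mk <- tryCatch(
    detect_rect_marker(img, config$whiteness_threshold, config$marker_angle_tol_deg,
                       real_width_m = config$marker_width_m,
                       real_height_m = config$marker_height_m),
    phenoError = function(e) NULL
  )
  white_thr <- config$whiteness_threshold / 255
  if (is.null(mk)) {
    # uncalibrated fallback: count bright blobs over the whole frame
    gray <- luminance(img)
    nonwhite <- img[, , 1] < white_thr | img[, , 2] < white_thr | img[, , 3] < white_thr
    mask <- clean_mask(otsu_foreground(gray, nonwhite), config$min_area_px, config$opening_radius)
    lm <- label_instances(mask, config$connectivity)
    traits <- list(count = lm$n_instances, density_per_m2 = NULL)
    return(pheno_result("wheat_head_pheno", calibration(), traits, config,
                        extra = list(marker = NULL)))
  }
  rec <- rectify_from_marker(img, mk)
  rimg <- rec$image
  cal <- rec$calibration
  # marker interior in the rectified frame
  tc <- rec$target_corners
  r0 <- min(tc[, "row"]); r1 <- max(tc[, "row"]); c0 <- min(tc[, "col"]); c1 <- max(tc[, "col"])
  gray <- luminance(rimg)
  interior <- matrix(FALSE, nrow(gray), ncol(gray))
  interior[max(1, ceiling(r0)):min(nrow(gray), floor(r1)),
           max(1, ceiling(c0)):min(ncol(gray), floor(c1))] <- TRUE
  nonwhite <- rimg[, , 1] < white_thr | rimg[, , 2] < white_thr | rimg[, , 3] < white_thr
  sel <- interior & nonwhite
  mask <- clean_mask(otsu_foreground(gray, sel), config$min_area_px, config$opening_radius)
  lm <- label_instances(mask, config$connectivity)
  lm <- split_adhesions(lm, config$solidity_threshold, config$peak_min_distance)
  heads <- measure_all(lm, cal)
  area_m2 <- config$marker_width_m * config$marker_height_m
  density <- lm$n_instances / area_m2
  traits <- list(
    count = lm$n_instances, density_per_m2 = density,
    mean_head_length_mm = if (nrow(heads)) mean(heads$length_mm) else NULL,
    mean_head_width_mm = if (nrow(heads)) mean(heads$width_mm) else NULL
  )
  if (!is.null(config$head_weight_g))
    traits$yield_kg_per_ha <- density * config$head_weight_g * 10
  pheno_result("wheat_head_pheno", cal, traits, config, records = heads,
               extra = list(marker = mk, homography = rec$homography,
                            labelmap = lm))
}
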