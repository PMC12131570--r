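#' Pixel-to-physical calibration
#'
#' @param mm_per_px physical length of one pixel in millimetres (`NA` for
#'   uncalibrated scenes).
#' @param source one of `"coin"`, `"marker"`, `"manual"`, `"none"`.
#' @return object of class `"pheno_calibration"`.
#' @export
calibration <- function(mm_per_px = NA_real_, source = c("none", "coin", "marker", "manual")) {
  source <- match.arg(source)
  if (source != "none" && (!is.finite(mm_per_px) || mm_per_px <= 0))
    pheno_error("pheno_invalid_parameter", "mm_per_px must be > 0 when source != 'none'")
  structure(list(mm_per_px = as.numeric(mm_per_px), source = source),
            class = "pheno_calibration")
}

#' @export
print.pheno_calibration <- function(x, ...) {
  if (x$source == "none") cat("<pheno_calibration> uncalibrated (pixel units)\n")
  else cat("<pheno_calibration> ", format(x$mm_per_px, digits = 6), " mm/px (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Detect a circular reference coin
#'
#' Binarizes the luminance channel with the Otsu threshold, labels connected
#' components, and fits a circle to the most circular component with
#' `circularity >= circularity_min` and radius `>= min_radius_px`
#' (circularity = \eqn{4\pi A / P^2}, clamped to 1 for rasterized discs whose
#' traced boundary slightly under-measures the true perimeter). Ties are
#' broken by the larger radius.
#'
#' @param img RGB array `[h, w, 3]` in `[0,1]`.
#' @param min_radius_px minimum acceptable coin radius (>= 3).
#' @param circularity_min minimum circularity to qualify (default 0.85).
#' @return object of class `"pheno_circle"`: list with `center` (row, col),
#'   `radius` (px) and `circularity`.
#' @export
detect_coin <- function(img, min_radius_px = 20, circularity_min = 0.85) {
  stopifnot(min_radius_px >= 3)
  gray <- luminance(img)
  t <- otsu_threshold(gray_histogram(gray))
  mask <- (gray > t) * 1L
  if (sum(mask) == 0)
    pheno_error("pheno_coin_not_found", "no foreground pixels; coin not found")
  lm <- label_instances(mask, connectivity = 8)
  best <- NULL
  min_area <- pi * min_radius_px^2 / 4   # cheap pre-filter
  for (i in seq_len(lm$n_instances)) {
    area <- sum(lm$labels == i)
    if (area < min_area) next
    per <- chain_perimeter(lm$contours[[i]])
    if (per <= 0) next
    circ <- min(1, 4 * pi * area / per^2)
    radius <- sqrt(area / pi)
    # half-pixel tolerance: subpixel disc placement shifts the rasterized
    # equivalent radius by up to ~0.5 px either way
    if (circ < circularity_min || radius < min_radius_px - 0.5) next
    if (is.null(best) || circ > best$circularity + 1e-12 ||
        (abs(circ - best$circularity) <= 1e-12 && radius > best$radius)) {
      pix <- which(lm$labels == i, arr.ind = TRUE)
      best <- structure(list(center = colMeans(pix), radius = radius, circularity = circ),
                        class = "pheno_circle")
    }
  }
  if (is.null(best))
    pheno_error("pheno_coin_not_found", "no sufficiently circular component; coin not found")
  best
}

#' Scale factor from a detected coin
#'
#' @param detection a [detect_coin()] result.
#' @param coin_diameter_mm physical coin diameter in mm (> 0); the coin type
#'   is user configuration (default 25 mm).
#' @return a `"pheno_calibration"` with `mm_per_px = diameter / (2 radius)`.
#' @export
scale_from_coin <- function(detection, coin_diameter_mm = 25) {
  if (!is.finite(coin_diameter_mm) || coin_diameter_mm <= 0)
    pheno_error("pheno_invalid_parameter", "coin_diameter_mm must be > 0")
  calibration(coin_diameter_mm / (2 * detection$radius), "coin")
}

#' Detect a white rectangular field marker
#'
#' Thresholds near-white pixels (all channels at or above
#' `whiteness_threshold` on the 8-bit scale), takes the largest connected
#' component, and extracts a quadrilateral from its convex hull by snapping
#' the minimum-area rotated rectangle corners to the nearest hull vertices.
#' The marker is verified to be convex with every interior angle within
#' `angle_tol_deg` of 90 degrees.
#'
#' @param img RGB array `[h, w, 3]` in `[0,1]`.
#' @param whiteness_threshold 8-bit level (0-255) above which a channel
#'   counts as white (default 200).
#' @param angle_tol_deg interior-angle tolerance for the rectangle check.
#' @param real_width_m,real_height_m physical marker dimensions (metres),
#'   required later for rectification.
#' @return object of class `"pheno_quad"`: `corners` (4 x 2, (row, col),
#'   counter-clockwise from top-left), `area_px`, `real_width_m`,
#'   `real_height_m`.
#' @export
detect_rect_marker <- function(img, whiteness_threshold = 200, angle_tol_deg = 15,
                               real_width_m = NA_real_, real_height_m = NA_real_) {
  thr <- whiteness_threshold / 255
  white <- (img[, , 1] >= thr) & (img[, , 2] >= thr) & (img[, , 3] >= thr)
  if (!any(white))
    pheno_error("pheno_marker_not_found", "no near-white pixels; marker not found")
  lab <- EBImage::bwlabel(white * 1)
  sizes <- tabulate(as.integer(lab))
  big <- which.max(sizes)
  pix <- which(matrix(as.integer(lab), nrow(white)) == big, arr.ind = TRUE)
  hp <- hull_points(pix[, c(2, 1), drop = FALSE])           # (x=col, y=row)
  if (nrow(hp) < 4)
    pheno_error("pheno_marker_not_found", "white region is not quadrilateral")
  rect <- min_area_rect(hp)
  corners <- rect_corners(rect)
  quad <- t(apply(corners, 1, function(p) {
    hp[which.min((hp[, 1] - p[1])^2 + (hp[, 2] - p[2])^2), ]
  }))
  quad <- order_quad(quad)
  ang <- quad_interior_angles(quad)
  if (any(abs(ang - 90) > angle_tol_deg))
    pheno_error("pheno_marker_not_found",
                sprintf("quadrilateral fails right-angle check (angles: %s)",
                        paste(round(ang, 1), collapse = ", ")))
  area <- abs(polygon_area_signed(quad))
  if (area <= 0)
    pheno_error("pheno_marker_not_found", "degenerate marker contour")
  structure(list(
    corners = cbind(row = quad[, 2], col = quad[, 1]),
    area_px = area, real_width_m = real_width_m, real_height_m = real_height_m
  ), class = "pheno_quad")
}

# corners of a rotated rect (list from min_area_rect) as 4 x 2 (x, y)
#' @noRd
rect_corners <- function(rect) {
  a <- rect$angle_deg * pi / 180
  u <- c(cos(a), sin(a)); v <- c(-u[2], u[1])
  hl <- rect$length / 2; hw <- rect$width / 2
  ctr <- rect$center
  rbind(
    ctr + hl * u + hw * v, ctr - hl * u + hw * v,
    ctr - hl * u - hw * v, ctr + hl * u - hw * v
  )
}

# order quad vertices counter-clockwise (image coords, y down) starting at
# the corner nearest the image origin (top-left)
#' @noRd
order_quad <- function(q) {
  ctr <- colMeans(q)
  ang <- atan2(q[, 2] - ctr[2], q[, 1] - ctr[1])
  q <- q[order(ang), , drop = FALSE]            # clockwise on screen = CCW mathwise
  start <- which.min(q[, 1] + q[, 2])
  q[((seq_len(4) + start - 2) %% 4) + 1, , drop = FALSE]
}

#' @noRd
quad_interior_angles <- function(q) {
  vapply(1:4, function(i) {
    p <- q[i, ]; a <- q[(i %% 4) + 1, ]; b <- q[((i + 2) %% 4) + 1, ]
    angle_at_vertex(p, a, b)
  }, numeric(1))
}

# 4-point homography by direct linear transform; maps (x, y) src -> dst.
# Returns 3 x 3 matrix H with H[3,3] = 1.
#' @noRd
homography_4pt <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e)
    pheno_error("pheno_invalid_marker", "degenerate (collinear) corner configuration"))
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' @noRd
apply_homography <- function(H, pts) {
  if (nrow(pts) == 0) return(matrix(numeric(0), 0, 2))
  p <- H %*% rbind(t(pts), rep(1, nrow(pts)))
  cbind(p[1, ] / p[3, ], p[2, ] / p[3, ])
}

#' Rectify an image from a detected rectangular marker
#'
#' Computes the homography mapping the marker corners to an axis-aligned
#' rectangle whose pixel aspect ratio equals `real_width_m / real_height_m`
#' (area-preserving, placed at the marker's bounding-box origin), warps the
#' image by inverse nearest-neighbour mapping, and derives the scale from the
#' rectified marker width. Applying the function to an already-rectified
#' image gives a homography within a pixel of the identity.
#'
#' @param img RGB array `[h, w, 3]`.
#' @param marker a [detect_rect_marker()] result with real dimensions set.
#' @return list with `image` (warped array, same size), `calibration`
#'   (`"pheno_calibration"`, source `"marker"`), `homography` (3 x 3, maps
#'   source (x, y) to rectified (x, y)), and `target_corners` (4 x 2
#'   (row, col)).
#' @export
rectify_from_marker <- function(img, marker) {
  if (!is.finite(marker$real_width_m) || !is.finite(marker$real_height_m) ||
      marker$real_width_m <= 0 || marker$real_height_m <= 0)
    pheno_error("pheno_invalid_parameter", "marker real dimensions must be set and > 0")
  src <- cbind(marker$corners[, "col"], marker$corners[, "row"])   # (x, y)
  if (collinear_triple(src))
    pheno_error("pheno_invalid_marker", "marker corners are collinear")
  aspect <- marker$real_width_m / marker$real_height_m
  w_px <- sqrt(marker$area_px * aspect)    # pixel length of the physical width
  h_px <- sqrt(marker$area_px / aspect)
  x0 <- min(src[, 1]); y0 <- min(src[, 2])
  # two candidate correspondences (physical width horizontal or vertical in
  # the image), both ordered like order_quad() output (top-left, then the
  # top side); pick the one displacing the detected corners least, which
  # also makes re-rectification the identity
  cand <- list(
    rbind(c(x0, y0), c(x0 + w_px, y0), c(x0 + w_px, y0 + h_px), c(x0, y0 + h_px)),
    rbind(c(x0, y0), c(x0 + h_px, y0), c(x0 + h_px, y0 + w_px), c(x0, y0 + w_px))
  )
  disp <- vapply(cand, function(d) sum((d - src)^2), numeric(1))
  dst <- cand[[which.min(disp)]]
  H <- homography_4pt(src, dst)
  warped <- warp_image(img, H)
  cal <- calibration(marker$real_width_m * 1000 / w_px, "marker")
  list(image = warped, calibration = cal, homography = H,
       target_corners = cbind(row = dst[, 2], col = dst[, 1]))
}

#' @noRd
collinear_triple <- function(pts, tol = 1e-6) {
  for (i in 1:2) for (j in (i + 1):3) for (k in (j + 1):4) {
    cr <- (pts[j, 1] - pts[i, 1]) * (pts[k, 2] - pts[i, 2]) -
          (pts[j, 2] - pts[i, 2]) * (pts[k, 1] - pts[i, 1])
    if (abs(cr) < tol) return(TRUE)
  }
  FALSE
}

# inverse nearest-neighbour warp of img by homography H (src (x,y) -> dst)
#' @noRd
warp_image <- function(img, H) {
  h <- dim(img)[1]; w <- dim(img)[2]
  Hi <- solve(H)
  xy <- cbind(rep(1:w, each = h), rep(1:h, times = w))    # dst (x, y)
  sp <- apply_homography(Hi, xy)
  sr <- round(sp[, 2]); sc <- round(sp[, 1])
  ok <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  out <- array(0, dim(img))
  didx <- cbind(xy[ok, 2], xy[ok, 1])
  sidx <- cbind(sr[ok], sc[ok])
  for (ch in seq_len(dim(img)[3]))
    out[cbind(didx, ch)] <- img[cbind(sidx, ch)]
  out
}

#' Convert pixel measurements to physical units
#'
#' Lengths scale linearly in `mm_per_px`, areas quadratically, and count
#' densities (per pixel^2) convert to per-square-metre via
#' \eqn{(mm\_per\_px/1000)^{-2}}. With an uncalibrated scene (`source ==
#' "none"`) the pixel value is returned unchanged and flagged.
#'
#' @param value_px numeric value in pixels, pixels^2, or count per pixel^2.
#' @param kind `"length"`, `"area"`, or `"count_density"`.
#' @param cal a `"pheno_calibration"`.
#' @param inverse if `TRUE`, convert a physical value back to pixels.
#' @return numeric with attributes `unit` and `calibrated`.
#' @export
convert_units <- function(value_px, kind = c("length", "area", "count_density"),
                          cal, inverse = FALSE) {
  kind <- match.arg(kind)
  if (cal$source == "none") {
    unit <- switch(kind, length = "px", area = "px2", count_density = "per_px2")
    return(structure(value_px, unit = unit, calibrated = FALSE))
  }
  f <- switch(kind,
    length = cal$mm_per_px,
    area = cal$mm_per_px^2,
    count_density = (cal$mm_per_px / 1000)^-2
  )
  unit <- switch(kind, length = "mm", area = "mm2", count_density = "per_m2")
  val <- if (inverse) value_px / f else value_px * f
  structure(val, unit = unit, calibrated = TRUE)
}
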