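# Axis and angle computations. Generic point sets here are n x 2 matrices
# with columns (x, y); pipelines convert from (row, col) with x = col, y = row.

# normalize a direction vector: unit length, non-negative first component
# (tie: non-negative second)
#' @noRd
normalize_direction <- function(d) {
  n <- sqrt(sum(d^2))
  if (n == 0) pheno_error("pheno_degenerate", "zero-length direction")
  d <- d / n
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d
  d
}

# total-least-squares line through points: first principal component
#' @noRd
tls_line <- function(pts) {
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  sv <- svd(cen, nu = 0, nv = 2)
  list(point = ctr, direction = normalize_direction(sv$v[, 1]))
}

# perpendicular distance of points to line(point, direction)
#' @noRd
line_dist <- function(pts, point, direction) {
  dx <- pts[, 1] - point[1]; dy <- pts[, 2] - point[2]
  abs(dx * direction[2] - dy * direction[1])
}

#' Robust major-axis fit of a 2-D point set by RANSAC
#'
#' Standard two-point-sample RANSAC: repeatedly hypothesizes a line through
#' two random points, counts inliers within `inlier_tol_px`, keeps the
#' hypothesis with the most inliers, then refits by total least squares
#' (first principal component) on the inlier set. Deterministic for a given
#' `seed`; the global RNG state is left untouched.
#'
#' @param points n x 2 matrix (x, y), n >= 2.
#' @param iterations number of random hypotheses (default 200).
#' @param inlier_tol_px perpendicular distance tolerance (default 2).
#' @param seed RNG seed recorded in the output.
#' @return object of class `"pheno_line"`: `point` (on the line),
#'   `direction` (unit, sign-normalized), `inlier_count`, `seed`.
#' @export
ransac_major_axis <- function(points, iterations = 200, inlier_tol_px = 2, seed = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 2)
    pheno_error("pheno_invalid_input", "need at least 2 points")
  if (all(abs(points[, 1] - points[1, 1]) < 1e-12) &&
      all(abs(points[, 2] - points[1, 2]) < 1e-12))
    pheno_error("pheno_degenerate", "all points coincident")
  n <- nrow(points)
  best_inl <- NULL
  with_local_seed(seed, {
    for (it in seq_len(iterations)) {
      ij <- sample.int(n, 2)
      d <- points[ij[2], ] - points[ij[1], ]
      if (sum(d^2) < 1e-20) next
      d <- d / sqrt(sum(d^2))
      inl <- line_dist(points, points[ij[1], ], d) <= inlier_tol_px
      if (is.null(best_inl) || sum(inl) > sum(best_inl)) best_inl <- inl
    }
  })
  if (is.null(best_inl)) best_inl <- rep(TRUE, n)
  fit <- tls_line(points[best_inl, , drop = FALSE])
  structure(list(point = fit$point, direction = fit$direction,
                 inlier_count = sum(best_inl), seed = seed),
            class = "pheno_line")
}

#' Fit a polynomial axis through ordered instance centers
#'
#' Rotates the centers so their principal direction becomes the independent
#' axis, then least-squares fits a degree-`degree` polynomial. This is the
#' wheat-ear central axis (rachis) model: spikelet centers scatter around a
#' smooth curve that is nearly single-valued along the ear's principal
#' direction.
#'
#' @param centers n x 2 matrix (x, y), `n >= degree + 1`.
#' @param degree polynomial degree (default 3).
#' @return object of class `"pheno_polyaxis"`: `rotation` (2 x 2, original ->
#'   axis frame), `center`, `coefficients` (increasing powers), `domain`
#'   (range of the fitted coordinate), `rms` (fit residual), `degree`.
#' @export
fit_ear_axis <- function(centers, degree = 3) {
  centers <- as.matrix(centers)
  if (nrow(centers) < degree + 1)
    pheno_error("pheno_insufficient_data",
                sprintf("need at least %d centers for degree %d", degree + 1, degree))
  ctr <- colMeans(centers)
  cen <- sweep(centers, 2, ctr)
  sv <- svd(cen, nu = 0, nv = 2)
  d1 <- normalize_direction(sv$v[, 1])
  R <- rbind(d1, c(-d1[2], d1[1]))          # rows: axis u, normal v
  uv <- cen %*% t(R)
  X <- outer(uv[, 1], 0:degree, `^`)
  cf <- qr.solve(X, uv[, 2])
  res <- uv[, 2] - X %*% cf
  structure(list(rotation = R, center = ctr, coefficients = as.numeric(cf),
                 domain = range(uv[, 1]), rms = sqrt(mean(res^2)), degree = degree),
            class = "pheno_polyaxis")
}

# evaluate polynomial axis at coordinates u: returns (x, y) in original frame
#' @noRd
polyaxis_eval <- function(axis, u) {
  v <- outer(u, 0:axis$degree, `^`) %*% axis$coefficients
  cbind(u, as.numeric(v)) %*% axis$rotation + matrix(axis$center, length(u), 2, byrow = TRUE)
}

# unit tangent of the axis at coordinate u, in the original frame
#' @noRd
polyaxis_tangent <- function(axis, u) {
  dg <- axis$degree
  slope <- as.numeric(outer(u, 0:(dg - 1), `^`) %*% (axis$coefficients[-1] * seq_len(dg)))
  t(vapply(slope, function(s) normalize_direction(c(1, s) %*% axis$rotation), numeric(2)))
}

# axis-frame coordinates (u, v) of points
#' @noRd
polyaxis_project <- function(axis, pts) {
  sweep(as.matrix(pts), 2, axis$center) %*% t(axis$rotation)
}

#' Zhang-Suen skeletonization of a binary mask
#'
#' Iterates the two Zhang-Suen sub-passes (neighbour count 2..6, exactly one
#' 0-to-1 transition around the 8-neighbourhood, and the two directional
#' deletion conditions) until no pixel is removed. The skeleton is a subset
#' of the input foreground; re-thinning a skeleton changes nothing.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 integer matrix of the one-pixel-wide skeleton.
#' @export
zhang_suen_thin <- function(mask) {
  full <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0) return(full)
  # thinning is local: work on the foreground bounding box (1 px pad)
  rr <- range(fg[, 1]); cc <- range(fg[, 2])
  r0 <- max(1L, rr[1] - 1L); r1 <- min(nrow(mask), rr[2] + 1L)
  c0 <- max(1L, cc[1] - 1L); c1 <- min(ncol(mask), cc[2] + 1L)
  p <- matrix(as.integer(mask[r0:r1, c0:c1] > 0), r1 - r0 + 1L)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours clockwise from north: p2 N, p3 NE, p4 E, p5 SE, p6 S, p7 SW, p8 W, p9 NW
      p2 <- mat_shift(p,  1,  0); p3 <- mat_shift(p,  1, -1)
      p4 <- mat_shift(p,  0, -1); p5 <- mat_shift(p, -1, -1)
      p6 <- mat_shift(p, -1,  0); p7 <- mat_shift(p, -1,  1)
      p8 <- mat_shift(p,  0,  1); p9 <- mat_shift(p,  1,  1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1)
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 & p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      else
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 & p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      if (any(cond)) { p[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  full[r0:r1, c0:c1] <- p
  full
}

#' Angle at a vertex between two rays
#'
#' Arccosine of the normalized dot product of `p1 - vertex` and
#' `p2 - vertex`, in degrees within `[0, 180]`.
#'
#' @param vertex,p1,p2 length-2 numeric vectors (consistent 2-D coordinates).
#' @return angle in degrees.
#' @examples
#' angle_at_vertex(c(0, 0), c(1, 0), c(0, 1))   # 90
#' @export
angle_at_vertex <- function(vertex, p1, p2) {
  u <- p1 - vertex; v <- p2 - vertex
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    pheno_error("pheno_degenerate", "ray endpoint coincides with vertex")
  acos(clamp(sum(u * v) / (nu * nv), -1, 1)) * 180 / pi
}

#' Keypoint set for flag-leaf angle measurement
#'
#' The three detected organ keypoints are the stem base `A`, the spike tip
#' `B`, and the leaf node `C`; a leaf angle additionally needs a
#' leaf-direction reference `L` (e.g. the leaf bounding-box center or tip),
#' supplied explicitly.
#'
#' @param A,B,C,L length-2 numeric vectors; `A`, `B`, `C` pairwise distinct,
#'   `L` optional (`NULL`).
#' @return object of class `"pheno_keypoints"`.
#' @export
keypoint_triple <- function(A, B, C, L = NULL) {
  pts <- list(A = A, B = B, C = C)
  for (i in 1:2) for (j in (i + 1):3)
    if (all(abs(pts[[i]] - pts[[j]]) < 1e-12))
      pheno_error("pheno_invalid_input", "keypoints A, B, C must be pairwise distinct")
  structure(list(A = as.numeric(A), B = as.numeric(B), C = as.numeric(C),
                 L = if (is.null(L)) NULL else as.numeric(L)),
            class = "pheno_keypoints")
}

#' Flag-leaf angle from keypoints
#'
#' In mode `"node_stem_leaf"` (default) the angle is measured at the leaf
#' node `C` between the stem direction toward the spike tip (`C` to `B`) and
#' the leaf reference (`C` to `L`). In mode `"stem_axis_leaf"` it is the
#' angle between the whole stem axis `A` to `B` and the leaf vector `C` to
#' `L`. Which convention matches a given manual protocol is a measurement
#' choice; both are provided.
#'
#' @param k a [keypoint_triple()] with `L` set.
#' @param mode `"node_stem_leaf"` or `"stem_axis_leaf"`.
#' @return angle in degrees `[0, 180]`.
#' @export
flag_leaf_angle <- function(k, mode = c("node_stem_leaf", "stem_axis_leaf")) {
  mode <- match.arg(mode)
  if (is.null(k$L))
    pheno_error("pheno_insufficient_keypoints", "leaf reference point L is required")
  if (mode == "node_stem_leaf") {
    angle_at_vertex(k$C, k$B, k$L)
  } else {
    u <- k$B - k$A; v <- k$L - k$C
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) pheno_error("pheno_degenerate", "zero-length vector")
    acos(clamp(sum(u * v) / (nu * nv), -1, 1)) * 180 / pi
  }
}

#' Angle between a spikelet axis and the local ear-axis tangent
#'
#' Projects the spikelet center into the ear-axis frame, evaluates the axis
#' tangent at that coordinate (clamped to the fitted domain), and returns the
#' angle between the spikelet's major-axis direction and the tangent, folded
#' to `[0, 90]` (chirality is not distinguished).
#'
#' @param spikelet_axis a `"pheno_line"` from [ransac_major_axis()].
#' @param ear_axis a `"pheno_polyaxis"` from [fit_ear_axis()].
#' @param center spikelet center (x, y).
#' @param domain_tol_px how far beyond the fitted domain `center` may project
#'   before the request is rejected as extrapolation (default 10 px).
#' @return angle in degrees `[0, 90]`.
#' @export
spikelet_angle <- function(spikelet_axis, ear_axis, center, domain_tol_px = 10) {
  uv <- polyaxis_project(ear_axis, matrix(center, 1, 2))
  u <- uv[1, 1]
  dom <- ear_axis$domain
  if (u < dom[1] - domain_tol_px || u > dom[2] + domain_tol_px)
    pheno_error("pheno_out_of_domain", "center projects beyond the fitted ear-axis domain")
  u <- clamp(u, dom[1], dom[2])
  tang <- polyaxis_tangent(ear_axis, u)[1, ]
  d <- spikelet_axis$direction
  ang <- acos(clamp(abs(sum(d * tang)), 0, 1)) * 180 / pi
  ang
}
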