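# Convex-hull and rotated-rectangle helpers shared by segmentation (solidity
# gating) and morphometry (length/width). Points are n x 2 (x, y).

# convex hull vertices in counter-clockwise order (y-down image coords make
# chull() output clockwise in math terms; order is irrelevant for callers)
#' @noRd
hull_points <- function(pts) {
  if (nrow(pts) <= 2) return(pts)
  pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
}

# Count how many of `pts` lie inside (or on) the convex polygon `poly`.
# Convexity is assumed; a point is inside iff it is on the same side of
# every edge (tolerance for points exactly on an edge).
#' @noRd
count_in_convex <- function(poly, pts, tol = 1e-9) {
  n <- nrow(poly)
  if (n == 1) return(sum(abs(pts[, 1] - poly[1, 1]) < tol & abs(pts[, 2] - poly[1, 2]) < tol))
  inside <- rep(TRUE, nrow(pts))
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- poly[j, 1] - poly[i, 1]; ey <- poly[j, 2] - poly[i, 2]
    cr <- ex * (pts[, 2] - poly[i, 2]) - ey * (pts[, 1] - poly[i, 1])
    if (sgn == 0) {
      s <- sign(cr[abs(cr) > tol])
      if (length(s)) sgn <- s[1]
    }
    if (sgn != 0) inside <- inside & (sgn * cr >= -tol)
  }
  sum(inside)
}

# Minimum-area rotated bounding rectangle by rotating calipers over hull
# edges. Returns list(length, width, angle_deg, center) where length >= width
# are the side EXTENTS of the point set (add pixel footprint at call sites).
#' @noRd
min_area_rect <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) == 1)
    return(list(length = 0, width = 0, angle_deg = 0, center = pts[1, ]))
  hp <- hull_points(pts)
  if (nrow(hp) <= 2 || abs(polygon_area_signed(hp)) < 1e-12) {
    # collinear: extent along principal direction, zero width
    d <- hp[which.max(rowSums((hp - matrix(hp[1, ], nrow(hp), 2, byrow = TRUE))^2)), ] - hp[1, ]
    len <- sqrt(sum(d^2))
    u <- d / len
    proj <- as.matrix(pts) %*% u
    return(list(length = diff(range(proj)), width = 0,
                angle_deg = atan2(u[2], u[1]) * 180 / pi,
                center = colMeans(pts[c(which.min(proj), which.max(proj)), , drop = FALSE])))
  }
  best <- NULL
  n <- nrow(hp)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    u <- e / sqrt(sum(e^2))          # edge direction
    v <- c(-u[2], u[1])              # normal
    pu <- hp %*% u; pv <- hp %*% v
    du <- diff(range(pu)); dv <- diff(range(pv))
    if (is.null(best) || du * dv < best$area - 1e-12) {
      cu <- mean(range(pu)); cv <- mean(range(pv))
      best <- list(
        area = du * dv,
        length = max(du, dv), width = min(du, dv),
        angle_deg = if (du >= dv) atan2(u[2], u[1]) * 180 / pi else atan2(v[2], v[1]) * 180 / pi,
        center = c(cu * u[1] + cv * v[1], cu * u[2] + cv * v[2])
      )
    }
  }
  best[c("length", "width", "angle_deg", "center")]
}

# Perimeter of a closed 8-connected boundary chain (n x 2). Raw (1, sqrt(2))
# step weights overestimate digitized smooth boundaries by ~5.5% (a circle's
# compactness would come out ~0.90); the Kulpa-corrected weights 0.948
# (axial) / 1.343 (diagonal) are unbiased for digitized circles and keep a
# disc's compactness at ~1. Longer jumps (degenerate contours) fall back to
# the Euclidean step length.
#' @noRd
chain_perimeter <- function(chain) {
  n <- nrow(chain)
  if (n < 2) return(0)
  idx <- c(seq_len(n), 1L)
  dr <- abs(diff(chain[idx, 1, drop = TRUE])); dc <- abs(diff(chain[idx, 2, drop = TRUE]))
  s <- dr + dc
  axial <- s == 1; diag <- s == 2 & dr == 1
  other <- !(axial | diag)
  0.948 * sum(axial) + 1.343 * sum(diag) +
    if (any(other)) sum(sqrt(dr[other]^2 + dc[other]^2)) else 0
}
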