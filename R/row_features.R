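# Maize kernel row features: PCA alignment of the detected kernel centroids
# followed by 1-D K-means on the cross-axis coordinate. Rows on an ear are
# defined by position across the ear's long axis, so clustering the single
# cross-axis coordinate (rather than raw 2-D points) cannot split long rows
# lengthwise.

#' Align a kernel point set with its principal axis
#'
#' Centers the points and rotates them so the first principal component (the
#' ear's long axis) becomes the x-axis. The rotation sign is normalized so
#' the span in +x from the first point is maximal, making the output
#' deterministic under input reordering of symmetric sets.
#'
#' @param points n x 2 matrix (x, y), n >= 2, not all coincident.
#' @return list with `points` (aligned n x 2), `rotation` (2 x 2 applied on
#'   the right to centered points), `center`, `angle_deg` (rotation applied,
#'   mod 180).
#' @export
pca_align <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2)
    pheno_error("pheno_invalid_input", "need at least 2 points")
  if (all(abs(sweep(points, 2, points[1, ])) < 1e-12))
    pheno_error("pheno_degenerate", "all points coincident")
  ctr <- colMeans(points)
  cen <- sweep(points, 2, ctr)
  sv <- svd(cen, nu = 0, nv = 2)
  d1 <- sv$v[, 1]
  R <- cbind(d1, c(-d1[2], d1[1]))           # columns: new x, new y axes
  al <- cen %*% R
  if (max(al[, 1]) - al[1, 1] < al[1, 1] - min(al[, 1])) {
    al <- -al                                 # 180-degree flip keeps det(R) = 1
    R <- -R
  }
  ang <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  list(points = al, rotation = R, center = ctr, angle_deg = ang %% 180)
}

# deterministic farthest-point ("k-means++-style") initial centers for 1-D data
#' @noRd
farthest_point_init <- function(y, k) {
  ctrs <- y[which.min(y)]
  while (length(ctrs) < k) {
    d <- vapply(y, function(v) min(abs(v - ctrs)), numeric(1))
    ctrs <- c(ctrs, y[which.max(d)])
  }
  ctrs
}

#' @noRd
kmeans_1d <- function(y, centers) {
  km <- tryCatch(
    suppressWarnings(stats::kmeans(y, centers = matrix(centers, ncol = 1),
                                   iter.max = 100, algorithm = "Lloyd")),
    error = function(e) NULL
  )
  km
}

#' Cluster kernels into rows along the cross-axis coordinate
#'
#' Runs 1-D K-means on the aligned points' y coordinate for each candidate
#' `k` in `[k_min, k_max]`, using a deterministic farthest-point
#' initialization plus `n_init - 1` seeded random restarts, and selects the
#' `k` maximizing the mean silhouette width (`k = 1` is allowed only when
#' `k_max = 1`). Deterministic given `seed`.
#'
#' @param aligned n x 2 matrix from [pca_align()] (or any points whose second
#'   column is the cross-axis coordinate).
#' @param k_min,k_max candidate row-count range (`1 <= k_min <= k_max`;
#'   `k_max` is capped at the number of distinct cross-axis values).
#' @param seed RNG seed for the restarts.
#' @param n_init number of initializations per `k` (default 10).
#' @return list with `assignments` (integer vector), `k`, `silhouette`
#'   (mean width at the chosen `k`, `NA` for `k = 1`), `seed`.
#' @export
cluster_rows <- function(aligned, k_min = 4, k_max = 24, seed = 1, n_init = 10) {
  y <- as.matrix(aligned)[, 2]
  n_distinct <- length(unique(y))
  if (k_min < 1 || k_min > k_max)
    pheno_error("pheno_invalid_parameter", "need 1 <= k_min <= k_max")
  k_max <- min(k_max, n_distinct)
  if (k_min > k_max)
    pheno_error("pheno_invalid_parameter", "k_min exceeds the number of distinct cross-axis values")
  if (k_max == 1)
    return(list(assignments = rep(1L, length(y)), k = 1L, silhouette = NA_real_, seed = seed))
  ks <- max(k_min, 2):k_max
  dy <- stats::dist(y)
  best <- NULL
  with_local_seed(seed, {
    for (k in ks) {
      km_best <- NULL
      for (init in seq_len(n_init)) {
        ctrs <- if (init == 1) farthest_point_init(y, k)
                else sample(unique(y), k)
        km <- kmeans_1d(y, ctrs)
        if (!is.null(km) && (is.null(km_best) || km$tot.withinss < km_best$tot.withinss - 1e-12))
          km_best <- km
      }
      if (is.null(km_best)) next
      sil <- mean(cluster::silhouette(km_best$cluster, dy)[, 3])
      if (is.null(best) || sil > best$sil + 1e-12)
        best <- list(k = k, sil = sil, cluster = km_best$cluster)
    }
  })
  if (is.null(best))
    pheno_error("pheno_degenerate", "no valid clustering found")
  list(assignments = as.integer(best$cluster), k = as.integer(best$k),
       silhouette = best$sil, seed = seed)
}

#' Row features from clustered kernel points
#'
#' Orders rows by their mean cross-axis coordinate and reports the visible
#' kernel count, visible row count, and kernels per row. Counts always
#' conserve: `sum(kernels_per_row) == visible_kernel_count == nrow(points)`.
#' Only the rows on the imaged face are counted; if a whole-ear estimate is
#' wanted, apply an explicit user-chosen multiplier to `visible_row_count`.
#'
#' @param assignments integer cluster id per point.
#' @param points the (aligned) n x 2 point matrix.
#' @return object of class `"pheno_rowfeatures"`: `visible_kernel_count`,
#'   `visible_row_count`, `kernels_per_row` (ordered along the cross-axis),
#'   `mean_kernels_per_row`.
#' @export
extract_row_features <- function(assignments, points) {
  points <- as.matrix(points)
  if (length(assignments) != nrow(points) || anyNA(assignments))
    pheno_error("pheno_invalid_input", "every point must be assigned to exactly one row")
  ids <- sort(unique(assignments))
  ybar <- vapply(ids, function(i) mean(points[assignments == i, 2]), numeric(1))
  ord <- ids[order(ybar)]
  per_row <- vapply(ord, function(i) sum(assignments == i), integer(1))
  structure(list(
    visible_kernel_count = length(assignments),
    visible_row_count = length(per_row),
    kernels_per_row = as.integer(per_row),
    mean_kernels_per_row = mean(per_row)
  ), class = "pheno_rowfeatures")
}

#' @export
print.pheno_rowfeatures <- function(x, ...) {
  cat("<pheno_rowfeatures> ", x$visible_kernel_count, " kernels in ",
      x$visible_row_count, " visible rows (mean ",
      round(x$mean_kernels_per_row, 2), "/row)\n", sep = "")
  cat("  kernels per row:", paste(x$kernels_per_row, collapse = " "), "\n")
  invisible(x)
}
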