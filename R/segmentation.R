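#' Otsu threshold of an 8-bit grayscale histogram
#'
#' Returns the level \eqn{t} maximizing the between-class variance
#' \eqn{\omega_0(t)\,\omega_1(t)\,(\mu_0(t)-\mu_1(t))^2} of the two-class
#' split (background \eqn{\le t}, foreground \eqn{> t}). Ties are broken by
#' the lowest \eqn{t}.
#'
#' @param counts integer vector of 256 histogram counts for levels 0..255
#'   (see [gray_histogram()]).
#' @return integer threshold level in 0..255; foreground pixels are those
#'   strictly above it.
#' @examples
#' h <- integer(256); h[51] <- 100; h[201] <- 100   # mass at levels 50, 200
#' otsu_threshold(h)
#' @export
otsu_threshold <- function(counts) {
  if (length(counts) != 256L || any(counts < 0) || sum(counts) <= 0)
    pheno_error("pheno_invalid_input", "counts must be 256 non-negative values with positive sum")
  lv <- 0:255
  w <- counts / sum(counts)
  w0 <- cumsum(w)
  mu <- cumsum(w * lv)
  mu_t <- mu[256]
  # sigma_b^2(t) = (mu_T w0 - mu)^2 / (w0 (1 - w0)) = w0 w1 (mu0 - mu1)^2
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  which.max(sb) - 1L
}

#' Validate HSV channel bounds
#'
#' Bounds for bounded-HSV segmentation. Hue is in degrees `[0, 360)` and the
#' hue interval may wrap around 0 (e.g. a red band `[340, 20]`), denoted by
#' `lower["h"] > upper["h"]`. Saturation and value are in `[0, 1]`.
#'
#' @param lower,upper numeric length-3 vectors `(h, s, v)`.
#' @return list with elements `lower`, `upper`, class `"pheno_hsv_bounds"`.
#' @export
hsv_bounds <- function(lower, upper) {
  stopifnot(length(lower) == 3, length(upper) == 3)
  if (lower[2] > upper[2] || lower[3] > upper[3])
    pheno_error("pheno_invalid_input", "saturation/value lower bounds must not exceed upper bounds")
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "pheno_hsv_bounds")
}

#' Binary mask of pixels inside an HSV band
#'
#' A pixel is foreground iff hue, saturation and value all fall inside
#' `bounds`; the hue test wraps across 0 degrees when `lower_h > upper_h`.
#'
#' @param img RGB array `[h, w, 3]` in `[0,1]`.
#' @param bounds a [hsv_bounds()] object (or list with `lower`, `upper`).
#' @return integer 0/1 matrix `[h, w]`.
#' @export
hsv_in_range <- function(img, bounds) {
  ch <- image_hsv(img)
  lo <- bounds$lower; hi <- bounds$upper
  hue_ok <- if (lo[1] <= hi[1]) ch$h >= lo[1] & ch$h <= hi[1]
            else ch$h >= lo[1] | ch$h <= hi[1]
  m <- hue_ok & ch$s >= lo[2] & ch$s <= hi[2] & ch$v >= lo[3] & ch$v <= hi[3]
  matrix(as.integer(m), nrow(ch$h), ncol(ch$h))
}

#' Morphological cleanup of a binary mask
#'
#' Opening with a disc structuring element followed by removal of connected
#' components smaller than `min_area_px`. With `opening_radius = 0` and
#' `min_area_px = 0` this is the identity.
#'
#' @param mask 0/1 matrix.
#' @param min_area_px minimum component area (pixels^2) to keep.
#' @param opening_radius disc radius (pixels) of the opening element.
#' @return cleaned 0/1 integer matrix.
#' @export
clean_mask <- function(mask, min_area_px = 25, opening_radius = 0) {
  stopifnot(min_area_px >= 0, opening_radius >= 0)
  m <- (mask > 0) * 1
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, shape = "disc")
    m <- EBImage::opening(m, brush)
  }
  if (min_area_px > 0) {
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= min_area_px)
    m <- matrix(as.integer(as.integer(lab) %in% keep & lab > 0), nrow(m), ncol(m))
  }
  matrix(as.integer(m > 0), nrow(mask), ncol(mask))
}

#' Otsu foreground of a selected region, with a contrast guard
#'
#' Applies the Otsu threshold to the gray levels under `sel` and returns the
#' foreground mask. When the region has no genuine bimodality — the
#' foreground/background mean separation falls below `min_contrast` 8-bit
#' levels, as on a noise-only background — an empty mask is returned instead
#' of shattering the noise into spurious objects.
#'
#' @param gray integer matrix of 8-bit levels (see [luminance()]).
#' @param sel logical matrix restricting the histogram and the output.
#' @param min_contrast minimum foreground-background mean separation (levels).
#' @return integer 0/1 matrix.
#' @export
otsu_foreground <- function(gray, sel = NULL, min_contrast = 20) {
  if (is.null(sel)) sel <- matrix(TRUE, nrow(gray), ncol(gray))
  vals <- gray[sel]
  empty <- matrix(0L, nrow(gray), ncol(gray))
  if (!length(vals)) return(empty)
  t <- otsu_threshold(gray_histogram(vals))
  fg <- gray > t & sel
  bgv <- vals[vals <= t]
  if (!any(fg) || !length(bgv) || mean(gray[fg]) - mean(bgv) < min_contrast)
    return(empty)
  matrix(as.integer(fg), nrow(gray), ncol(gray))
}

# union-find merge of diagonally adjacent 4-connected labels -> 8-connectivity
#' @noRd
merge_diagonal_labels <- function(lab) {
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (sh in list(c(1, 1), c(1, -1))) {
    nb <- mat_shift(lab, sh[1], sh[2])
    sel <- lab > 0 & nb > 0 & lab != nb
    if (any(sel)) {
      prs <- unique(cbind(as.integer(lab[sel]), as.integer(nb[sel])))
      for (r in seq_len(nrow(prs))) {
        a <- find(prs[r, 1]); b <- find(prs[r, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# per-label closed contours, 1-based (row, col), counter-clockwise in image
# coordinates (x = col, y = row, y down)
#' @noRd
trace_contours <- function(labels, n) {
  if (n == 0) return(list())
  oc <- EBImage::ocontour(labels)
  lapply(seq_len(n), function(i) {
    ch <- oc[[i]] + 1L   # ocontour is 0-based in the matrix's own indices
    ch <- cbind(row = ch[, 1], col = ch[, 2])
    # normalize orientation: CCW in (x=col, y=row) screen coords = negative
    # shoelace area in (col, row) with y down
    if (nrow(ch) >= 3 && polygon_area_signed(ch[, c(2, 1)]) > 0)
      ch <- ch[rev(seq_len(nrow(ch))), , drop = FALSE]
    ch
  })
}

#' Label connected components of a binary mask
#'
#' Produces an instance label map: integer labels 1..N (0 = background), each
#' label one connected component under the chosen connectivity, with a traced
#' closed boundary contour per instance.
#'
#' @param mask 0/1 matrix.
#' @param connectivity 4 or 8 (default 8; 4 fragments anti-aliased borders).
#' @return object of class `"pheno_labelmap"`: list with `labels` (integer
#'   matrix), `n_instances`, and `contours` (list of closed `(row, col)`
#'   chains, 1-based, counter-clockwise).
#' @export
label_instances <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8))
    pheno_error("pheno_invalid_parameter", "connectivity must be 4 or 8")
  lab <- EBImage::bwlabel((mask > 0) * 1)   # 4-connected
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8) lab <- merge_diagonal_labels(lab)
  # renumber in first-pixel (column-major) order for determinism
  u <- unique(lab[lab > 0])
  if (length(u)) {
    relab <- integer(max(u)); relab[u] <- seq_along(u)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  n <- length(u)
  structure(list(labels = lab, n_instances = n, contours = trace_contours(lab, n)),
            class = "pheno_labelmap")
}

#' @export
print.pheno_labelmap <- function(x, ...) {
  cat("<pheno_labelmap> ", nrow(x$labels), "x", ncol(x$labels),
      " px, ", x$n_instances, " instance(s)\n", sep = "")
  invisible(x)
}

# square max filter of radius r via iterated shift-pmax (separable)
#' @noRd
max_filter_sq <- function(m, r) {
  r <- as.integer(r)
  out <- m
  for (k in seq_len(r)) out <- pmax(out, mat_shift(m, 0, k, -Inf), mat_shift(m, 0, -k, -Inf))
  res <- out
  for (k in seq_len(r)) res <- pmax(res, mat_shift(out, k, 0, -Inf), mat_shift(out, -k, 0, -Inf))
  res
}

# Distance-transform peaks. Local maxima are detected under a square max
# filter of half `min_distance` (so a deeply fused small object still shows
# its own maximum), duplicates closer than `min_distance` are suppressed
# keeping the larger distance value, and finally peaks with no genuine
# saddle between them are merged: if the straight-path minimum between two
# peaks stays above `rel_saddle` of the lower peak value (as on the flat
# ridge of one elongated object) they belong to one object. The relative
# test scales from small seeds to large fruit.
#' @noRd
find_dt_peaks <- function(d, min_distance, rel_saddle = 0.9) {
  r <- max(2L, as.integer(ceiling(min_distance / 2)))
  mf <- max_filter_sq(d, r)
  cand <- which(d > 0 & d >= mf - 1e-9, arr.ind = TRUE)
  if (nrow(cand) == 0) return(cand)
  vals <- d[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kc <- cand[keep, , drop = FALSE]
    d2 <- (kc[, 1] - cand[i, 1])^2 + (kc[, 2] - cand[i, 2])^2
    if (all(d2 >= min_distance^2)) keep[i] <- TRUE
  }
  pk <- cand[keep, , drop = FALSE]
  # saddle (prominence) merge, strongest peak first
  i <- 2L
  while (i <= nrow(pk)) {
    drop <- FALSE
    for (j in seq_len(i - 1L)) {
      n <- max(2L, ceiling(sqrt(sum((pk[i, ] - pk[j, ])^2))))
      rr <- round(seq(pk[j, 1], pk[i, 1], length.out = n))
      cc <- round(seq(pk[j, 2], pk[i, 2], length.out = n))
      saddle <- min(d[cbind(rr, cc)])
      if (saddle >= rel_saddle * d[pk[i, 1], pk[i, 2]]) { drop <- TRUE; break }
    }
    if (drop) pk <- pk[-i, , drop = FALSE] else i <- i + 1L
  }
  pk
}

# rasterized solidity: instance area / number of pixel centers inside the
# convex hull of the instance's pixel centers. Exactly 1 for any convex
# rendered shape (see vignette).
#' @noRd
instance_solidity <- function(pix) {
  if (nrow(pix) < 3) return(1)
  hp <- hull_points(pix[, c(2, 1), drop = FALSE])   # (x=col, y=row)
  if (nrow(hp) <= 2) return(1)
  rr <- range(pix[, 1]); cc <- range(pix[, 2])
  grid <- cbind(
    x = rep(cc[1]:cc[2], each = rr[2] - rr[1] + 1),
    y = rep(rr[1]:rr[2], times = cc[2] - cc[1] + 1)
  )
  hull_n <- count_in_convex(hp, grid)
  if (hull_n <= 0) return(1)
  min(1, nrow(pix) / hull_n)
}

#' Split touching instances by distance-transform watershed
#'
#' Resolves residual adhesion between touching objects: every instance whose
#' solidity (area over convex-hull area) falls below `solidity_threshold` is
#' re-segmented by finding peaks of its Euclidean distance transform
#' (separated by at least `peak_min_distance`) and growing marker-controlled
#' watershed regions from them. Instances at or above the threshold pass
#' through unchanged. Output labels are renumbered contiguously; the union of
#' foreground pixels is preserved exactly and the instance count never
#' decreases.
#'
#' @param labelmap a [label_instances()] result.
#' @param solidity_threshold gate below which an instance is split
#'   (default 0.985; convex rendered shapes have rasterized solidity exactly 1,
#'   while near-collinear touching ellipse pairs reach 0.98).
#' @param peak_min_distance minimum separation (pixels) between watershed
#'   seeds; about half the expected object minor axis.
#' @return a new `"pheno_labelmap"`.
#' @export
split_adhesions <- function(labelmap, solidity_threshold = 0.985, peak_min_distance = 8) {
  lab <- labelmap$labels
  out <- matrix(0L, nrow(lab), ncol(lab))
  nxt <- 0L
  for (i in seq_len(labelmap$n_instances)) {
    pix <- which(lab == i, arr.ind = TRUE)
    sol <- instance_solidity(pix)
    if (sol >= solidity_threshold || nrow(pix) < 9) {
      nxt <- nxt + 1L
      out[pix] <- nxt
      next
    }
    # work on padded bounding box
    rr <- range(pix[, 1]); cc <- range(pix[, 2])
    sub <- matrix(0, rr[2] - rr[1] + 3, cc[2] - cc[1] + 3)
    sub[cbind(pix[, 1] - rr[1] + 2L, pix[, 2] - cc[1] + 2L)] <- 1
    d <- EBImage::distmap(sub)
    d <- matrix(as.numeric(d), nrow(sub), ncol(sub))
    pk <- find_dt_peaks(d, peak_min_distance)
    if (nrow(pk) <= 1) {
      nxt <- nxt + 1L
      out[pix] <- nxt
      next
    }
    seeds <- matrix(0L, nrow(sub), ncol(sub))
    seeds[pk] <- seq_len(nrow(pk))
    ws <- EBImage::propagate(d, seeds, mask = sub > 0, lambda = 1e-4)
    ws <- matrix(as.integer(ws), nrow(sub), ncol(sub))
    # any stray unassigned foreground keeps the nearest (first) seed label
    ws[sub > 0 & ws == 0] <- 1L
    for (s in seq_len(nrow(pk))) {
      sp <- which(ws == s, arr.ind = TRUE)
      if (nrow(sp) == 0) next
      nxt <- nxt + 1L
      out[cbind(sp[, 1] + rr[1] - 2L, sp[, 2] + cc[1] - 2L)] <- nxt
    }
  }
  structure(list(labels = out, n_instances = nxt, contours = trace_contours(out, nxt)),
            class = "pheno_labelmap")
}
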