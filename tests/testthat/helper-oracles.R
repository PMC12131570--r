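# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they stay independent
# of the implementation paths they check.

# exhaustive-search Otsu: loop over every threshold, compute class weights
# and means directly from histogram slices
otsu_bruteforce <- function(counts) {
  n <- sum(counts)
  best_t <- 0L
  best_v <- -Inf
  for (t in 0:255) {
    idx0 <- 1:(t + 1)
    n0 <- sum(counts[idx0]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) v <- 0
    else {
      mu0 <- sum((0:t) * counts[idx0]) / n0
      mu1 <- sum(((t + 1):255) * counts[-idx0]) / n1
      v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    }
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# circularity of a rasterized shape from first principles: area = pixel
# count, perimeter = count of pixel edges bordering background (the exact
# boundary length of the pixel-square polygon)
circularity_bruteforce <- function(mask) {
  area <- sum(mask > 0)
  m <- (mask > 0) * 1L
  pad <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  per <- 0
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- pad * 0L
    nb[(1 + max(0, sh[1])):(nrow(pad) + min(0, sh[1])),
       (1 + max(0, sh[2])):(ncol(pad) + min(0, sh[2]))] <-
      pad[(1 - min(0, sh[1])):(nrow(pad) - max(0, sh[1])),
          (1 - min(0, sh[2])):(ncol(pad) - max(0, sh[2]))]
    per <- per + sum(pad == 1 & nb == 0)
  }
  4 * pi * area / per^2
}

# angle via atan2 of the two ray bearings, folded to [0, 180]
angle_atan2_oracle <- function(vertex, p1, p2) {
  a1 <- atan2(p1[2] - vertex[2], p1[1] - vertex[1])
  a2 <- atan2(p2[2] - vertex[2], p2[1] - vertex[1])
  d <- abs(a1 - a2) %% (2 * pi)
  if (d > pi) d <- 2 * pi - d
  d * 180 / pi
}

# optimal 1-D k-partition by dynamic programming on the sorted values,
# minimizing within-cluster sum of squares; returns cluster id per input
# point (clusters ordered along the axis)
kmeans1d_dp_oracle <- function(y, k) {
  ord <- order(y)
  s <- y[ord]
  n <- length(s)
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  ssq <- function(i, j) {  # within-SS of s[i..j]
    su <- cs[j] - if (i > 1) cs[i - 1] else 0
    sq <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    sq - su^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  cut <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- ssq(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    for (i in m:j) {
      v <- cost[m - 1, i - 1] + ssq(i, j)
      if (v < cost[m, j] - 1e-12) { cost[m, j] <- v; cut[m, j] <- i }
    }
  }
  lab_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- if (m == 1) 1L else cut[m, j]
    lab_sorted[i:j] <- m
    j <- i - 1
  }
  lab <- integer(n)
  lab[ord] <- lab_sorted
  lab
}

# rotate a point set (n x 2, (x, y)) about the origin by +deg (CCW in (x, y))
rotate_pts <- function(pts, deg) {
  a <- deg * pi / 180
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)   # applied as p %*% R
  as.matrix(pts) %*% R
}
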