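#' @noRd
pheno_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "phenoError", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Run code with a temporary RNG seed, restoring global RNG state
#' @noRd
with_local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# FNV-1a 32-bit hash of a serialized R object; hex string.
# Used for provenance config hashes (stable across runs for identical config).
#' @noRd
fnv1a32 <- function(obj) {
  bytes <- serialize(obj, NULL, version = 2)
  # skip serialization header (R version bytes vary across installs)
  bytes <- bytes[-seq_len(14L)]
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^32 - (h %% 2^32 >= 2^31) * 2^32), b)
    h <- (as.numeric(h) %% 2^32) * 16777619
    h <- h %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# shift a matrix by (dr, dc), zero padding
#' @noRd
mat_shift <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# clamp helper
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# shoelace signed area of polygon given as n x 2 matrix (x, y)
#' @noRd
polygon_area_signed <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Coefficient of determination between predictions and reference values
#'
#' Computes \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, the metric used by the
#' soundness harness to compare pipeline outputs against synthetic ground
#' truth (and, in field use, against manual measurements).
#'
#' @param predicted numeric vector of predicted values.
#' @param reference numeric vector of reference (ground-truth) values.
#' @return A single number \eqn{\le 1}; 1 for perfect prediction, 0 for a
#'   predictor no better than the reference mean, negative when worse.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 3))   # 1
#' r_squared(rep(2, 3), c(1, 2, 3))    # 0
#' @export
r_squared <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    pheno_error("pheno_invalid_input", "predicted and reference must have equal length")
  if (length(reference) < 2)
    pheno_error("pheno_invalid_input", "need at least 2 values")
  sst <- sum((reference - mean(reference))^2)
  if (sst == 0)
    pheno_error("pheno_undefined", "reference variance is zero; R^2 undefined")
  1 - sum((predicted - reference)^2) / sst
}
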