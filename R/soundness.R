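# End-to-end soundness harness: for each pipeline, generate scenes whose
# generative parameters vary across a realistic range, run the pipeline, and
# score predicted traits against ground truth with R^2 — the same
# predicted-vs-reference evaluation style used to validate the tools against
# manual measurements, with synthetic truth standing in for the manual
# reference.

#' Predicted-versus-truth soundness scores for every pipeline
#'
#' Generates `n_scenes` synthetic scenes per pipeline with varying
#' generative parameters (counts, sizes, angles, green fractions, densities,
#' row structure), runs the corresponding pipeline, and reports [r_squared()]
#' between predictions and generative ground truth for a count trait and a
#' continuous trait per pipeline (the leaf-angle tool, a pure angle
#' computation, contributes only a continuous score).
#'
#' @param n_scenes scenes per pipeline (default 100).
#' @param seed base RNG seed; scene `i` of a pipeline uses a seed derived
#'   from it.
#' @param pipelines subset of
#'   `c("seed", "tomato", "spikelet", "canopy", "corn", "wheat_head",
#'   "leaf_angle")`.
#' @return `data.frame` with columns `pipeline`, `trait`, `kind`
#'   (`"count"` or `"continuous"`), `r2`, `n`.
#' @export
soundness_scores <- function(n_scenes = 100, seed = 1,
                             pipelines = c("seed", "tomato", "spikelet", "canopy",
                                           "corn", "wheat_head", "leaf_angle")) {
  pipelines <- match.arg(pipelines, several.ok = TRUE)
  out <- list()
  add <- function(pipeline, trait, kind, pred, ref) {
    out[[length(out) + 1]] <<- data.frame(
      pipeline = pipeline, trait = trait, kind = kind,
      r2 = r_squared(pred, ref), n = length(pred)
    )
  }
  sd2 <- function(i, k) seed * 1000L + k * 101L + i   # per-scene derived seed

  if ("seed" %in% pipelines) {
    pred_n <- ref_n <- pred_len <- ref_len <- numeric(n_scenes)
    for (i in seq_len(n_scenes)) {
      pars <- with_local_seed(sd2(i, 1), list(
        n = sample(20:80, 1), u = stats::runif(1, 0.75, 1.25)
      ))
      sc <- gen_seed_tray(n_seeds = pars$n, semi_major = c(8, 14) * pars$u,
                          seed = sd2(i, 2))
      r <- run_seed_pheno(sc$image, pheno_config(seed = sd2(i, 3)))
      pred_n[i] <- r$traits$count
      ref_n[i] <- sc$gt$count
      pred_len[i] <- r$traits$stats$mean[r$traits$stats$trait == "length_px"]
      ref_len[i] <- mean(2 * sc$gt$seeds$a)
    }
    add("seed", "count", "count", pred_n, ref_n)
    add("seed", "mean_length_px", "continuous", pred_len, ref_len)
  }

  if ("tomato" %in% pipelines) {
    pred_n <- ref_n <- pred_d <- ref_d <- numeric(n_scenes)
    for (i in seq_len(n_scenes)) {
      n <- with_local_seed(sd2(i, 4), sample(3:12, 1))
      sc <- gen_tomato_scene(n_tomatoes = n, seed = sd2(i, 5))
      r <- run_tomato_pheno(sc$image, pheno_config(seed = sd2(i, 6)))
      pred_n[i] <- r$traits$count
      ref_n[i] <- n
      pred_d[i] <- mean(r$records$equivalent_diameter_px)
      ref_d[i] <- mean(2 * sc$gt$tomatoes$radius)
    }
    add("tomato", "count", "count", pred_n, ref_n)
    add("tomato", "mean_diameter_px", "continuous", pred_d, ref_d)
  }

  if ("spikelet" %in% pipelines) {
    pred_n <- ref_n <- pred_a <- ref_a <- numeric(n_scenes)
    for (i in seq_len(n_scenes)) {
      pars <- with_local_seed(sd2(i, 7), list(
        n = sample(12:24, 1), ang = stats::runif(1, 20, 50)
      ))
      sc <- gen_spikelet_ear(n_spikelets = pars$n, angle_deg = pars$ang,
                             seed = sd2(i, 8))
      r <- run_spikelet_pheno(sc$image, pheno_config(seed = sd2(i, 9)))
      pred_n[i] <- r$traits$count
      ref_n[i] <- pars$n
      pred_a[i] <- if (is.null(r$traits$median_angle_deg)) NA else r$traits$median_angle_deg
      ref_a[i] <- pars$ang
    }
    add("spikelet", "count", "count", pred_n, ref_n)
    ok <- !is.na(pred_a)
    add("spikelet", "median_angle_deg", "continuous", pred_a[ok], ref_a[ok])
  }

  if ("canopy" %in% pipelines) {
    pred_area <- ref_area <- pred_g <- ref_g <- numeric(n_scenes)
    for (i in seq_len(n_scenes)) {
      pars <- with_local_seed(sd2(i, 10), list(
        radius = stats::runif(1, 90, 200), gf = stats::runif(1, 0.2, 0.9),
        kind = sample(c("disc", "star"), 1)
      ))
      sc <- gen_canopy(pars$kind, radius = pars$radius, green_fraction = pars$gf,
                       seed = sd2(i, 11))
      r <- run_canopy_pheno(sc$image, pheno_config(seed = sd2(i, 12)))
      pred_area[i] <- r$traits$area_px2
      ref_area[i] <- sc$gt$area_px
      pred_g[i] <- r$traits$green_ratio
      ref_g[i] <- sc$gt$green_fraction
    }
    add("canopy", "area_px2", "count", pred_area, ref_area)
    add("canopy", "green_ratio", "continuous", pred_g, ref_g)
  }

  if ("corn" %in% pipelines) {
    pred_k <- ref_k <- pred_n <- ref_n <- numeric(n_scenes)
    for (i in seq_len(n_scenes)) {
      pars <- with_local_seed(sd2(i, 13), list(
        rows = sample(c(8, 10, 12, 14, 16, 18), 1), cols = sample(25:35, 1),
        rot = stats::runif(1, 0, 180)
      ))
      sc <- gen_corn_lattice(n_rows = pars$rows, n_cols = pars$cols,
                             jitter_frac = 0.1, rotation_deg = pars$rot,
                             seed = sd2(i, 14))
      r <- run_corn_pheno(sc$gt$points, pheno_config(seed = sd2(i, 15)))
      pred_k[i] <- r$traits$visible_row_count
      ref_k[i] <- pars$rows
      pred_n[i] <- r$traits$mean_kernels_per_row
      ref_n[i] <- pars$cols
    }
    add("corn", "row_count", "count", pred_k, ref_k)
    add("corn", "mean_kernels_per_row", "continuous", pred_n, ref_n)
  }

  if ("wheat_head" %in% pipelines) {
    pred_n <- ref_n <- pred_d <- ref_d <- numeric(n_scenes)
    for (i in seq_len(n_scenes)) {
      pars <- with_local_seed(sd2(i, 16), list(
        dens = sample(30:90, 1), rot = stats::runif(1, -8, 8),
        persp = stats::runif(2, -3e-5, 3e-5)
      ))
      sc <- gen_wheat_plot(density_per_m2 = pars$dens, rotation_deg = pars$rot,
                           perspective = pars$persp, seed = sd2(i, 17))
      r <- run_wheat_head(sc$image, pheno_config(seed = sd2(i, 18)))
      pred_n[i] <- r$traits$count
      ref_n[i] <- sc$gt$n_inside
      pred_d[i] <- r$traits$density_per_m2
      ref_d[i] <- sc$gt$density_per_m2
    }
    add("wheat_head", "count", "count", pred_n, ref_n)
    add("wheat_head", "density_per_m2", "continuous", pred_d, ref_d)
  }

  if ("leaf_angle" %in% pipelines) {
    pred_a <- ref_a <- numeric(n_scenes)
    for (i in seq_len(n_scenes)) {
      kp <- with_local_seed(sd2(i, 19), {
        repeat {
          A <- stats::runif(2, 0, 100); B <- stats::runif(2, 0, 100)
          C <- stats::runif(2, 0, 100); L <- stats::runif(2, 0, 100)
          if (sum((B - C)^2) > 1 && sum((L - C)^2) > 1) break
        }
        keypoint_triple(A, B, C, L)
      })
      r <- run_leaf_angle(kp, pheno_config(seed = sd2(i, 20)))
      pred_a[i] <- r$traits$angle_deg
      ref_a[i] <- angle_at_vertex(kp$C, kp$B, kp$L)
    }
    add("leaf_angle", "angle_deg", "continuous", pred_a, ref_a)
  }

  do.call(rbind, out)
}
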