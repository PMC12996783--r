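# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force scans, closed forms, and direct
# evaluation of the Gaussian bump model.

# 4-connected component labelling by breadth-first flood fill
oracle_label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
              mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            queue <- c(queue, list(q))
          }
        }
      }
    }
  }
  lab
}

# canonical form of a labelling: list of sorted pixel-index sets
oracle_component_sets <- function(lab) {
  sets <- lapply(seq_len(max(lab, 0)), function(l) sort(which(lab == l)))
  sets[order(vapply(sets, min, 0))]
}

# direct evaluation of the anisotropic Gaussian druse bump on the grid
oracle_bump_field <- function(n_bscans, n_ascans, bspacing, aspacing,
                              center_bscan, center_ascan,
                              sigma_b, sigma_a, amplitude) {
  f <- matrix(0, n_bscans, n_ascans)
  for (b in seq_len(n_bscans)) for (a in seq_len(n_ascans)) {
    db <- (b - center_bscan) * bspacing
    da <- (a - center_ascan) * aspacing
    f[b, a] <- amplitude * exp(-0.5 * (db / sigma_b)^2 - 0.5 * (da / sigma_a)^2)
  }
  f
}

# ground-truth average height for one seeded druse: per-section mean of the
# analytic bump over its own above-half-threshold footprint, averaged over
# sections (mirrors the measurement definition, computed from the model)
oracle_truth_height <- function(spec, seed_obj, amplitude,
                                half_threshold = 5) {
  bump <- oracle_bump_field(spec$n_bscans, spec$n_ascans,
                            spec$bscan_spacing_um, spec$ascan_spacing_um,
                            seed_obj$center_bscan, seed_obj$center_ascan,
                            seed_obj$sigma_bscan_um, seed_obj$sigma_ascan_um,
                            amplitude)
  fp <- which(bump >= half_threshold, arr.ind = TRUE)
  if (nrow(fp) == 0) return(NA_real_)
  per <- tapply(bump[fp], fp[, 1], mean)
  mean(per)
}

# closed-form Welch t statistic and two-tailed p value
oracle_welch <- function(x, y) {
  s1 <- var(x) / length(x); s2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(s1 + s2)
  df <- (s1 + s2)^2 / (s1^2 / (length(x) - 1) + s2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small drusen-free volume used by several tests
make_flat_volume <- function(n_bscans = 15, n_ascans = 64, thickness = 200,
                             bspacing = 109, aspacing = 17) {
  structure(
    list(eye_id = "e1", arm = "arm1", timepoint_months = 0,
         rpe_pos_depth_um = matrix(100, n_bscans, n_ascans),
         brm_depth_um = matrix(100 + thickness, n_bscans, n_ascans),
         bscan_spacing_um = bspacing, ascan_spacing_um = aspacing,
         axial_noise_sd_um = 0),
    class = "boundary_volume")
}

# thickness map built directly from a matrix, bypassing the generator
make_tmap <- function(m, bspacing = 109, aspacing = 17) {
  structure(m, class = c("thickness_map", "matrix", "array"),
            bscan_spacing_um = bspacing, ascan_spacing_um = aspacing,
            eye_id = "e1", arm = "arm1", timepoint_months = 0,
            n_flagged_negative = 0)
}
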