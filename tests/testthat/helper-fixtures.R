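# shared fixtures for the test suite

# small isotropic grid centred on the origin
test_grid <- function(shape = c(21, 21, 21), vox = 2) {
  aff <- diag(c(rep(vox, 3), 1))
  aff[1:3, 4] <- -(shape - 1) * vox / 2
  list(affine = aff, shape = as.integer(shape))
}

# brute-force sphere oracle: enumerate every voxel on the grid
brute_sphere_count <- function(center_mm, radius_mm, affine, shape) {
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                               k = 0:(shape[3] - 1)))
  w <- voxel_to_world(idx, affine)
  sum((w[, 1] - center_mm[1])^2 + (w[, 2] - center_mm[2])^2 +
        (w[, 3] - center_mm[3])^2 <= radius_mm^2 + 1e-9)
}

# small cohort for fast end-to-end checks
small_cohort <- function(...) {
  synthetic_cohort_config(n_subjects = 2, grid_shape = c(12, 12, 10),
                          n_volumes = 60, ...)
}

# run one subject's seed -> beta map -> stream strength chain
subject_stream_strengths <- function(cfg, s, parc, streams) {
  r <- generate_rest_run(cfg, s, parc = parc, streams = streams)
  nuis <- nuisance_set(r$motion, run = r$run, compartments = r$compartments)
  out <- list()
  for (i in seq_len(nrow(r$ground_truth$seed_sites))) {
    site <- r$ground_truth$seed_sites[i, ]
    sph <- build_sphere_roi(roi_spec(site$name, c(site$x, site$y, site$z),
                                     cfg$seed_radius_mm),
                            cfg$affine, cfg$grid_shape)
    ts <- first_eigenvariate(r$run, sph)
    bm <- seed_beta_map(r$run, ts, nuis, seed_name = site$name, subject = s)
    agg <- stream_strength(bm, r$parcellation, streams)$streams
    out[[i]] <- cbind(subject = s, seed = site$name,
                      agg[, c("stream", "value")])
  }
  do.call(rbind, out)
}
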