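#' Synthetic cohort configuration
#'
#' Describes a desk-scale multi-subject dataset with planted structure:
#' two latent "network" signals (dorsal and ventral), seed sites whose
#' timeseries load onto those latents, a toy cortical parcellation whose
#' dorsal/ventral parcels load onto the matching latent, geometric
#' compartment regions (white matter, CSF, out-of-brain) carrying shared
#' nuisance signals, and additive motion confounds.
#'
#' Default seed-site loadings plant a graded dorsal affinity
#' (EBA > LOC > FBA) on a common loading norm, the qualitative structure
#' the downstream interaction and classification analyses are designed to
#' detect.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param grid_shape Length-3 voxel grid (default 24 x 28 x 24).
#' @param voxel_size_mm Isotropic voxel size (default 2 mm).
#' @param tr_s Repetition time (default 2 s).
#' @param n_volumes Volumes per run (default 200).
#' @param seed_sites data.frame `name`, `x`, `y`, `z` (mm),
#'   `loading_dorsal`, `loading_ventral`; `NULL` for the default three
#'   sites.
#' @param parcel_loading Loading of parcel voxels on their stream's latent
#'   (default 0.6).
#' @param noise_sd Voxelwise AR(1) noise SD (default 1).
#' @param ar1_rho Temporal autocorrelation of noise and latents (default
#'   0.3).
#' @param motion_amplitude Random-walk step SD of the motion parameters
#'   (default 0.05 mm).
#' @param compartment_leak Coupling of in-brain voxels to the white-matter
#'   nuisance signal (default 0.1).
#' @param seed_radius_mm Radius of the planted seed spheres (default 4).
#' @param subject_jitter_vox Max per-axis voxel jitter of subject seed
#'   sites (default 1).
#' @param rng_seed Base RNG seed (default 1).
#' @return A `cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_subjects = 8,
                                    grid_shape = c(24, 28, 24),
                                    voxel_size_mm = 2,
                                    tr_s = 2,
                                    n_volumes = 200,
                                    seed_sites = NULL,
                                    parcel_loading = 0.6,
                                    noise_sd = 1,
                                    ar1_rho = 0.3,
                                    motion_amplitude = 0.05,
                                    compartment_leak = 0.1,
                                    seed_radius_mm = 4,
                                    subject_jitter_vox = 1,
                                    rng_seed = 1L) {
  stopifnot(n_subjects >= 1, length(grid_shape) == 3L, all(grid_shape >= 8),
            ar1_rho >= 0, ar1_rho < 1, noise_sd >= 0, n_volumes >= 2)
  grid_shape <- as.integer(grid_shape)
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- -(grid_shape - 1) * voxel_size_mm / 2
  if (is.null(seed_sites)) {
    # three sites on the mid-axial slab, separated along x
    xs <- ((c(0.22, 0.5, 0.78) * (grid_shape[1] - 1)) ) * voxel_size_mm +
      affine[1, 4]
    ymid <- affine[2, 4] + (grid_shape[2] - 1) * voxel_size_mm * 0.55
    zmid <- affine[3, 4] + (grid_shape[3] - 1) * voxel_size_mm * 0.5
    seed_sites <- data.frame(
      name = c("EBA", "LOC", "FBA"),
      x = xs, y = ymid, z = zmid,
      loading_dorsal = c(0.8, 0.5, 0.2),
      loading_ventral = c(0.3, 0.6, 0.8))
  }
  stopifnot(all(c("name", "x", "y", "z", "loading_dorsal",
                  "loading_ventral") %in% names(seed_sites)),
            all(is.finite(seed_sites$loading_dorsal)),
            all(is.finite(seed_sites$loading_ventral)))
  cfg <- list(n_subjects = as.integer(n_subjects), grid_shape = grid_shape,
              voxel_size_mm = voxel_size_mm, affine = affine, tr_s = tr_s,
              n_volumes = as.integer(n_volumes), seed_sites = seed_sites,
              parcel_loading = parcel_loading, noise_sd = noise_sd,
              ar1_rho = ar1_rho, motion_amplitude = motion_amplitude,
              compartment_leak = compartment_leak,
              seed_radius_mm = seed_radius_mm,
              subject_jitter_vox = as.integer(subject_jitter_vox),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "cohort_config"
  cfg
}

# deterministic per-subject, per-purpose RNG seed (kept well below 2^31)
subject_seed <- function(cfg, subject, offset = 0L) {
  (cfg$rng_seed * 10007L + subject * 101L + offset) %% 2147483629L
}

# unit-variance AR(1) process
ar1_series <- function(n, rho) {
  if (rho == 0) return(stats::rnorm(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n - 1) * sqrt(1 - rho^2)
  for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t - 1]
  x
}

#' Toy parcellation matching the packaged stream table
#'
#' Lays the 13 dorsal parcels out as tiles on a superior axial slab and the
#' 9 ventral parcels on an inferior slab of the synthetic grid, labelled
#' with the packaged atlas area names.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @param streams A `stream_table` (defaults to the packaged table).
#' @return A [parcellation_volume()].
#' @export
synth_parcellation <- function(cfg, streams = load_stream_table()) {
  d <- cfg$grid_shape
  lab <- array(0L, d)
  dorsal <- streams$area_name[streams$stream == "dorsal"]
  ventral <- streams$area_name[streams$stream == "ventral"]
  tile_slab <- function(names, k_range, start_label) {
    n_tiles <- length(names)
    ncol_t <- ceiling(sqrt(n_tiles))
    nrow_t <- ceiling(n_tiles / ncol_t)
    i_lo <- 2L; i_hi <- d[1] - 3L
    j_lo <- 2L; j_hi <- d[2] - 3L
    iw <- (i_hi - i_lo + 1L) %/% ncol_t
    jw <- (j_hi - j_lo + 1L) %/% nrow_t
    for (t in seq_len(n_tiles)) {
      ci <- (t - 1L) %% ncol_t
      cj <- (t - 1L) %/% ncol_t
      ii <- (i_lo + ci * iw):(i_lo + ci * iw + max(iw - 2L, 0L))
      jj <- (j_lo + cj * jw):(j_lo + cj * jw + max(jw - 2L, 0L))
      lab[ii + 1L, jj + 1L, k_range + 1L] <<- start_label + t - 1L
    }
  }
  k_dorsal <- (d[3] - 6L):(d[3] - 4L)
  k_ventral <- 3L:5L
  tile_slab(dorsal, k_dorsal, 1L)
  tile_slab(ventral, k_ventral, 100L)
  label_map <- c(stats::setNames(seq_along(dorsal), dorsal),
                 stats::setNames(99L + seq_along(ventral), ventral))
  parcellation_volume(lab, label_map, cfg$affine)
}

#' Geometric compartment masks for a synthetic grid
#'
#' White matter and CSF are fixed interior boxes on the mid-axial slab near
#' the grid edges; out-of-brain is the one-voxel outer shell.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @return Named list of [roi_mask()]s: `wm`, `csf`, `oob`.
#' @export
synth_compartments <- function(cfg) {
  d <- cfg$grid_shape
  kmid <- (d[3] %/% 2 - 2L):(d[3] %/% 2 + 1L)
  box <- function(ii, jj, kk) {
    as.matrix(expand.grid(i = ii, j = jj, k = kk))
  }
  wm <- box(1L:4L, 1L:4L, kmid)
  csf <- box((d[1] - 5L):(d[1] - 2L), 1L:4L, kmid)
  shell <- rbind(
    box(c(0L, d[1] - 1L), 0L:(d[2] - 1L), 0L:(d[3] - 1L)),
    box(0L:(d[1] - 1L), c(0L, d[2] - 1L), 0L:(d[3] - 1L)),
    box(0L:(d[1] - 1L), 0L:(d[2] - 1L), c(0L, d[3] - 1L)))
  shell <- unique(shell)
  list(wm = roi_mask_from_indices(wm, cfg$affine, d, "wm"),
       csf = roi_mask_from_indices(csf, cfg$affine, d, "csf"),
       oob = roi_mask_from_indices(shell, cfg$affine, d, "oob"))
}

# subject-specific jittered seed-site centres (mm), deterministic
subject_seed_sites <- function(cfg, subject) {
  set.seed(subject_seed(cfg, subject, 7L))
  sites <- cfg$seed_sites
  if (cfg$subject_jitter_vox > 0) {
    jit <- matrix(sample(seq(-cfg$subject_jitter_vox, cfg$subject_jitter_vox),
                         nrow(sites) * 3L, replace = TRUE),
                  ncol = 3L) * cfg$voxel_size_mm
    sites$x <- sites$x + jit[, 1]
    sites$y <- sites$y + jit[, 2]
    sites$z <- sites$z + jit[, 3]
  }
  sites
}

# random-walk motion parameters (n x 6)
gen_motion <- function(n, amplitude) {
  m <- apply(matrix(stats::rnorm(n * 6, sd = amplitude), n, 6), 2, cumsum)
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Generate one subject's synthetic resting-state run
#'
#' Voxel timeseries are built as loading-weighted sums of two independent
#' unit-variance AR(1) latent network signals (dorsal, ventral) plus AR(1)
#' Gaussian noise; voxels inside a seed-site sphere carry that site's
#' loadings, parcel voxels carry `parcel_loading` on their stream's
#' latent, compartment voxels carry dedicated nuisance signals, and motion
#' parameters are injected as additive confounds through fixed random
#' spatial weight maps. All ground truth is recorded.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @param subject Subject index (1-based).
#' @param parc Optional precomputed [synth_parcellation()] (rebuilt when
#'   `NULL`).
#' @param streams Stream table used for the parcellation.
#' @return List with `run` (4D [volume_image()]), `motion` (n x 6 matrix),
#'   `compartments` (mask list), `parcellation`, and `ground_truth`
#'   (subject seed sites, loadings, latents).
#' @export
generate_rest_run <- function(cfg, subject, parc = NULL,
                              streams = load_stream_table()) {
  d <- cfg$grid_shape
  nt <- cfg$n_volumes
  nvox <- prod(d)
  if (is.null(parc)) parc <- synth_parcellation(cfg, streams)
  comps <- synth_compartments(cfg)
  sites <- subject_seed_sites(cfg, subject)
  # site masks first (errors before any RNG draws for the data)
  site_masks <- lapply(seq_len(nrow(sites)), function(i) {
    build_sphere_roi(roi_spec(sites$name[i],
                              c(sites$x[i], sites$y[i], sites$z[i]),
                              cfg$seed_radius_mm),
                     cfg$affine, d)
  })
  set.seed(subject_seed(cfg, subject, 11L))
  latents <- cbind(dorsal = ar1_series(nt, cfg$ar1_rho),
                   ventral = ar1_series(nt, cfg$ar1_rho))
  comp_sig <- cbind(wm = ar1_series(nt, cfg$ar1_rho),
                    csf = ar1_series(nt, cfg$ar1_rho),
                    oob = ar1_series(nt, cfg$ar1_rho))
  motion <- gen_motion(nt, cfg$motion_amplitude)
  # loading maps
  Ld <- numeric(nvox); Lv <- numeric(nvox)
  lab <- as.integer(parc$label_data)
  dorsal_labels <- parc$label_map[streams$area_name[streams$stream == "dorsal"]]
  ventral_labels <- parc$label_map[streams$area_name[streams$stream == "ventral"]]
  Ld[lab %in% dorsal_labels] <- cfg$parcel_loading
  Lv[lab %in% ventral_labels] <- cfg$parcel_loading
  for (i in seq_len(nrow(sites))) {
    li <- mask_linear_index(site_masks[[i]])
    Ld[li] <- sites$loading_dorsal[i]
    Lv[li] <- sites$loading_ventral[i]
  }
  # signal: voxel x time
  X <- tcrossprod(cbind(Ld, Lv), latents)
  # compartment signals
  for (nm in c("wm", "csf", "oob")) {
    X[mask_linear_index(comps[[nm]]), ] <-
      X[mask_linear_index(comps[[nm]]), , drop = FALSE] +
      matrix(comp_sig[, nm], ncol = nt, nrow = roi_size(comps[[nm]]),
             byrow = TRUE)
  }
  if (cfg$compartment_leak > 0) {
    X <- X + cfg$compartment_leak *
      matrix(comp_sig[, "wm"], ncol = nt, nrow = nvox, byrow = TRUE)
  }
  # motion confounds via fixed random spatial weights
  if (cfg$motion_amplitude > 0) {
    W <- matrix(stats::rnorm(nvox * 6, sd = 0.5), nvox, 6)
    X <- X + W %*% t(motion)
  }
  # AR(1) observation noise
  if (cfg$noise_sd > 0) {
    E <- matrix(stats::rnorm(nvox * nt), nvox, nt)
    if (cfg$ar1_rho > 0) {
      r <- cfg$ar1_rho
      s <- sqrt(1 - r^2)
      for (t in 2:nt) E[, t] <- r * E[, t - 1] + s * E[, t]
    }
    X <- X + cfg$noise_sd * E
  }
  run <- volume_image(array(X, c(d, nt)), cfg$affine, tr_s = cfg$tr_s)
  list(run = run, motion = motion, compartments = comps, parcellation = parc,
       ground_truth = list(subject = subject, seed_sites = sites,
                           parcel_loading = cfg$parcel_loading,
                           latents = latents, compartment_signals = comp_sig))
}

#' Default localizer block design
#'
#' Alternating blocks of the three conditions (bodies, objects, scrambled)
#' with rest gaps, filling the run.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @param block_s Block duration (default 16 s).
#' @param rest_s Rest gap between blocks (default 8 s).
#' @return A [block_design()].
#' @export
default_block_design <- function(cfg, block_s = 16, rest_s = 8) {
  run_s <- cfg$n_volumes * cfg$tr_s
  conds <- c("bodies", "objects", "scrambled")
  onsets <- seq(rest_s, run_s - block_s, by = block_s + rest_s)
  df <- data.frame(condition = conds[(seq_along(onsets) - 1) %% 3 + 1],
                   onset = onsets, duration = block_s)
  block_design(df, run_duration_s = run_s)
}

#' Generate one subject's synthetic localizer run
#'
#' Condition-specific response amplitudes are added at the seed sites
#' (amplitude decaying with distance from the site centre so the planted
#' peak is unique), convolved with the same canonical HRF used by the
#' analysis GLM, on top of AR(1) noise and motion confounds.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @param subject Subject index.
#' @param design A [block_design()]; default [default_block_design()].
#' @param amplitudes Named list: per seed-site name, a named numeric vector
#'   of response amplitudes per condition. Default plants body selectivity
#'   at EBA/FBA sites and object selectivity at the LOC site.
#' @param amp_fwhm_mm Spatial FWHM of the planted amplitude profile.
#' @return List with `run`, `events` (data.frame), `motion`,
#'   `ground_truth`.
#' @export
generate_localizer_run <- function(cfg, subject,
                                   design = default_block_design(cfg),
                                   amplitudes = NULL,
                                   amp_fwhm_mm = 5) {
  if (is.null(amplitudes)) {
    # contrasts of ~4 amplitude units against unit noise give peak t values
    # around 10 over a 200-volume block run, typical of 1-back localizers
    amplitudes <- list(
      EBA = c(bodies = 6, objects = 2, scrambled = 1),
      LOC = c(bodies = 3, objects = 6, scrambled = 1),
      FBA = c(bodies = 5, objects = 2, scrambled = 1))
    amplitudes <- amplitudes[intersect(names(amplitudes),
                                       cfg$seed_sites$name)]
  }
  d <- cfg$grid_shape
  nt <- cfg$n_volumes
  nvox <- prod(d)
  sites <- subject_seed_sites(cfg, subject)
  conds <- unique(design$conditions$condition)
  reg <- vapply(conds, function(cc) {
    b <- design$conditions[design$conditions$condition == cc, , drop = FALSE]
    convolve_regressor(b$onset, b$duration, cfg$tr_s, nt)
  }, numeric(nt))
  set.seed(subject_seed(cfg, subject, 23L))
  motion <- gen_motion(nt, cfg$motion_amplitude)
  X <- matrix(0, nvox, nt)
  sigma <- amp_fwhm_mm / (2 * sqrt(2 * log(2)))
  grid_idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                    k = 0:(d[3] - 1)))
  world <- voxel_to_world(grid_idx, cfg$affine)
  for (nm in names(amplitudes)) {
    s <- sites[sites$name == nm, , drop = FALSE]
    if (nrow(s) == 0L) stop("no seed site named '", nm, "'")
    d2 <- (world[, 1] - s$x)^2 + (world[, 2] - s$y)^2 + (world[, 3] - s$z)^2
    prof <- exp(-d2 / (2 * sigma^2))
    prof[d2 > (3 * amp_fwhm_mm)^2] <- 0
    amp <- amplitudes[[nm]]
    for (cc in names(amp)) {
      if (!cc %in% conds) next
      X <- X + outer(prof * amp[[cc]], reg[, cc])
    }
  }
  if (cfg$motion_amplitude > 0) {
    W <- matrix(stats::rnorm(nvox * 6, sd = 0.5), nvox, 6)
    X <- X + W %*% t(motion)
  }
  if (cfg$noise_sd > 0) {
    E <- matrix(stats::rnorm(nvox * nt), nvox, nt)
    if (cfg$ar1_rho > 0) {
      r <- cfg$ar1_rho
      sfac <- sqrt(1 - r^2)
      for (t in 2:nt) E[, t] <- r * E[, t - 1] + sfac * E[, t]
    }
    X <- X + cfg$noise_sd * E
  }
  run <- volume_image(array(X, c(d, nt)), cfg$affine, tr_s = cfg$tr_s)
  list(run = run, events = design$conditions, motion = motion,
       ground_truth = list(subject = subject, seed_sites = sites,
                           amplitudes = amplitudes))
}

#' Generate synthetic tractography path-count records
#'
#' Streamline outcomes per (subject, seed, hemisphere) are drawn
#' multinomially over {dorsal, ventral, lost} with the stated per-seed
#' rates, optionally perturbed per subject by a lognormal factor.
#'
#' @param cfg A [synthetic_cohort_config()] (supplies `n_subjects` and the
#'   RNG stream).
#' @param ratios data.frame `seed`, `dorsal_rate`, `ventral_rate`; default
#'   plants the ventral-dominant pattern with graded dorsal affinity
#'   EBA > LOC > FBA.
#' @param total Total streamlines sampled per seed (default 5000).
#' @param hemispheres Hemisphere labels (default left and right).
#' @param subject_sd SD of the per-subject lognormal rate perturbation
#'   (default 0.15; 0 disables it).
#' @return List with `records` (data.frame `subject`, `seed`,
#'   `hemisphere`, `stream`, `count`, `total`) and `ground_truth` (the
#'   realized per-subject rates).
#' @export
generate_tract_counts <- function(cfg,
                                  ratios = data.frame(
                                    seed = c("EBA", "LOC", "FBA"),
                                    dorsal_rate = c(0.22, 0.12, 0.05),
                                    ventral_rate = c(0.30, 0.35, 0.45)),
                                  total = 5000,
                                  hemispheres = c("left", "right"),
                                  subject_sd = 0.15) {
  stopifnot(total >= 1, all(ratios$dorsal_rate >= 0),
            all(ratios$ventral_rate >= 0))
  if (any(ratios$dorsal_rate + ratios$ventral_rate > 1)) {
    stop("dorsal_rate + ventral_rate must not exceed 1")
  }
  set.seed(subject_seed(cfg, 0L, 31L))
  rows <- list(); truth <- list()
  for (s in seq_len(cfg$n_subjects)) {
    for (h in hemispheres) {
      for (i in seq_len(nrow(ratios))) {
        rd <- ratios$dorsal_rate[i]
        rv <- ratios$ventral_rate[i]
        if (subject_sd > 0) {
          rd <- rd * exp(stats::rnorm(1, sd = subject_sd))
          rv <- rv * exp(stats::rnorm(1, sd = subject_sd))
          scl <- rd + rv
          if (scl > 0.98) { rd <- rd / scl * 0.98; rv <- rv / scl * 0.98 }
        }
        cnt <- stats::rmultinom(1, size = total, prob = c(rd, rv, 1 - rd - rv))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, seed = ratios$seed[i], hemisphere = h,
          stream = c("dorsal", "ventral"), count = cnt[1:2], total = total)
        truth[[length(truth) + 1L]] <- data.frame(
          subject = s, seed = ratios$seed[i], hemisphere = h,
          dorsal_rate = rd, ventral_rate = rv)
      }
    }
  }
  list(records = do.call(rbind, rows),
       ground_truth = do.call(rbind, truth))
}
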