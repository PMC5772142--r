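#' Pipeline configuration
#'
#' Bundles the synthetic-cohort description with the analysis parameters:
#' seed/target sphere radius 4 mm, high-pass cutoff 128 s, smoothing FWHM
#' 6 mm for the exploratory group stage, 5000 fingerprint permutations,
#' k swept from 2 to 8, 20 boundary seed voxels, and a 3 mm
#' motion-exclusion threshold.
#'
#' @param cohort A [synthetic_cohort_config()].
#' @param sphere_radius_mm Seed/target sphere radius (default 4).
#' @param search_radius_mm Seed-localization search-sphere radius
#'   (default 15).
#' @param highpass_s High-pass cutoff (default 128).
#' @param smoothing_fwhm_mm Smoothing kernel for the exploratory
#'   whole-brain stage (default 6).
#' @param n_perm Fingerprint permutations (default 5000).
#' @param k_range k-NN sweep (default 2:8).
#' @param boundary_n Tractography boundary seed voxels (default 20).
#' @param motion_threshold_mm Motion exclusion threshold (default 3).
#' @param n_targets Number of synthetic fingerprint targets (default 13).
#' @param rng_seed Base RNG seed.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(cohort = synthetic_cohort_config(),
                            sphere_radius_mm = 4,
                            search_radius_mm = 15,
                            highpass_s = 128,
                            smoothing_fwhm_mm = 6,
                            n_perm = 5000,
                            k_range = 2:8,
                            boundary_n = 20,
                            motion_threshold_mm = 3,
                            n_targets = 13,
                            rng_seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  num_pos <- c(sphere_radius_mm = sphere_radius_mm,
               search_radius_mm = search_radius_mm,
               highpass_s = highpass_s, n_perm = n_perm,
               boundary_n = boundary_n,
               motion_threshold_mm = motion_threshold_mm,
               n_targets = n_targets)
  bad <- names(num_pos)[!is.finite(num_pos) | num_pos <= 0]
  if (length(bad)) stop("parameters must be positive: ",
                        paste(bad, collapse = ", "))
  if (smoothing_fwhm_mm < 0) stop("smoothing_fwhm_mm must be >= 0")
  if (length(k_range) < 1L || any(k_range < 1L) ||
      any(k_range != round(k_range))) {
    stop("invalid k_range: needs positive integers")
  }
  structure(list(cohort = cohort, sphere_radius_mm = sphere_radius_mm,
                 search_radius_mm = search_radius_mm,
                 highpass_s = highpass_s,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 n_perm = as.integer(n_perm), k_range = as.integer(k_range),
                 boundary_n = as.integer(boundary_n),
                 motion_threshold_mm = motion_threshold_mm,
                 n_targets = as.integer(n_targets),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; the `cohort` key
#' holds [synthetic_cohort_config()] arguments.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  y$cohort <- do.call(synthetic_cohort_config, cohort_args)
  do.call(pipeline_config, y)
}

#' Synthetic fingerprint target spheres from a parcellation
#'
#' Places a 4 mm target sphere at the centroid of each of the first
#' `n` parcels (alternating dorsal/ventral so both streams are sampled),
#' the synthetic analogue of the packaged coordinate table.
#'
#' @param parc A [parcellation_volume()].
#' @param streams A `stream_table`.
#' @param n Number of targets (default 13).
#' @param radius_mm Sphere radius.
#' @return List of [roi_spec()]s.
#' @export
synth_target_specs <- function(parc, streams, n = 13, radius_mm = 4) {
  # interleave dorsal and ventral parcels so both streams are sampled
  d_areas <- streams$area_name[streams$stream == "dorsal"]
  v_areas <- streams$area_name[streams$stream == "ventral"]
  m <- max(length(d_areas), length(v_areas))
  inter <- c(rbind(d_areas[seq_len(m)], v_areas[seq_len(m)]))
  inter <- inter[!is.na(inter)][seq_len(n)]
  lapply(inter, function(a) {
    msk <- parcel_mask(parc, a)
    ctr <- colMeans(voxel_to_world(msk$voxel_indices, parc$affine))
    roi_spec(a, ctr, radius_mm)
  })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the simulate, localize, connect, fingerprint, classify and
#' tract stages on a synthetic cohort, writing stage outputs (TSV) and a
#' run manifest (JSON, with a config hash and RNG seeds) into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run (localize onwards
#'   depends on simulate, which is always run).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("localize", "connect", "fingerprint",
                                    "classify", "tract"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  cfg <- config$cohort
  outputs <- character(0)
  results <- list()

  ## -- simulate ------------------------------------------------------
  say("stage: simulate")
  streams <- load_stream_table()
  parc <- synth_parcellation(cfg, streams)
  rest <- lapply(seq_len(cfg$n_subjects), function(s)
    generate_rest_run(cfg, s, parc = parc, streams = streams))
  keep <- vapply(rest, function(r)
    screen_motion(r$motion, config$motion_threshold_mm)$pass, logical(1))
  if (!all(keep)) {
    say(sum(!keep), " subject(s) excluded for motion")
  }
  rest <- rest[keep]
  subjects <- which(keep)
  truth <- lapply(rest, `[[`, "ground_truth")
  gt_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(lapply(truth, function(g)
    list(subject = g$subject, seed_sites = g$seed_sites)),
    gt_path, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, simulate = gt_path)
  results$simulate <- list(n_subjects = length(rest), subjects = subjects)

  ## -- localize ------------------------------------------------------
  seed_rows <- NULL
  if ("localize" %in% stages) {
    say("stage: localize")
    seed_rows <- list()
    for (i in seq_along(rest)) {
      loc <- generate_localizer_run(cfg, subjects[i])
      X <- build_design(block_design(loc$events,
                                     run_duration_s = cfg$n_volumes * cfg$tr_s),
                        cfg$tr_s, cfg$n_volumes, motion = loc$motion)
      fit <- fit_glm(loc$run, X, highpass_s = config$highpass_s)
      cn <- colnames(X)
      for (nm in cfg$seed_sites$name) {
        w <- numeric(length(cn))
        if (nm %in% c("EBA", "FBA")) {
          w[cn == "bodies"] <- 1; w[cn == "objects"] <- -1
        } else {
          w[cn == "objects"] <- 1; w[cn == "scrambled"] <- -1
        }
        tmap <- contrast_map(fit, w)
        site <- cfg$seed_sites[cfg$seed_sites$name == nm, ]
        sl <- localize_seed(tmap,
                            roi_spec(nm, c(site$x, site$y, site$z),
                                     config$search_radius_mm),
                            hemisphere = "left")
        seed_rows[[length(seed_rows) + 1L]] <- data.frame(
          subject = subjects[i], name = nm, hemisphere = "left",
          x = sl$coord_mm[1], y = sl$coord_mm[2], z = sl$coord_mm[3],
          t = sl$peak_stat)
      }
    }
    seed_rows <- do.call(rbind, seed_rows)
    p <- write_tsv(seed_rows, file.path(out_dir, "seed_locations.tsv"))
    outputs <- c(outputs, localize = p)
    results$localize <- seed_rows
  }

  ## -- connect -------------------------------------------------------
  beta_maps <- NULL
  if (any(c("connect", "fingerprint", "classify") %in% stages)) {
    say("stage: connect")
    beta_maps <- list()
    strength_rows <- list()
    for (i in seq_along(rest)) {
      r <- rest[[i]]
      nuis <- nuisance_set(r$motion, run = r$run,
                           compartments = r$compartments)
      for (nm in cfg$seed_sites$name) {
        coord <- if (!is.null(seed_rows)) {
          sr <- seed_rows[seed_rows$subject == subjects[i] &
                            seed_rows$name == nm, ]
          c(sr$x, sr$y, sr$z)
        } else {
          site <- r$ground_truth$seed_sites
          unlist(site[site$name == nm, c("x", "y", "z")])
        }
        sph <- build_sphere_roi(roi_spec(nm, coord, config$sphere_radius_mm),
                                cfg$affine, cfg$grid_shape)
        ts <- first_eigenvariate(r$run, sph)
        bm <- seed_beta_map(r$run, ts, nuis, highpass_s = config$highpass_s,
                            seed_name = nm, subject = subjects[i])
        beta_maps[[paste(subjects[i], nm, sep = "_")]] <- bm
        st <- stream_strength(bm, r$parcellation, streams)
        strength_rows[[length(strength_rows) + 1L]] <- cbind(
          subject = subjects[i], seed = nm, hemisphere = "left",
          st$streams[, c("stream", "value")])
      }
    }
    strengths <- do.call(rbind, strength_rows)
    p1 <- write_tsv(strengths, file.path(out_dir, "stream_strengths.tsv"))
    an <- repeated_anova(strengths, within = c("seed", "stream"))
    p2 <- write_tsv(an, file.path(out_dir, "rs_anova.tsv"))
    outputs <- c(outputs, connect = p1)
    results$connect <- list(strengths = strengths, anova = an)
  }

  ## -- fingerprint ---------------------------------------------------
  if ("fingerprint" %in% stages) {
    say("stage: fingerprint")
    targets <- synth_target_specs(parc, streams, n = config$n_targets,
                                  radius_mm = config$sphere_radius_mm)
    fp <- list()
    for (key in names(beta_maps)) {
      f <- extract_fingerprint(beta_maps[[key]], targets)
      fp[[key]] <- f
    }
    seeds <- cfg$seed_sites$name
    arm_mats <- lapply(seeds, function(nm) {
      do.call(rbind, fp[paste(subjects, nm, sep = "_")])
    })
    names(arm_mats) <- seeds
    pairs <- utils::combn(seeds, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      tr <- fingerprint_permutation_test(arm_mats[[pairs[1, j]]],
                                         arm_mats[[pairs[2, j]]],
                                         n_perm = config$n_perm,
                                         rng_seed = config$rng_seed + j)
      data.frame(seed_a = pairs[1, j], seed_b = pairs[2, j],
                 observed_d = tr$observed_d, p = tr$p, n_perm = tr$n_perm)
    }))
    fp_long <- do.call(rbind, lapply(names(fp), function(key) {
      parts <- strsplit(key, "_")[[1]]
      data.frame(subject = parts[1], seed = parts[2],
                 target = names(fp[[key]]), value = as.numeric(fp[[key]]))
    }))
    p1 <- write_tsv(fp_long, file.path(out_dir, "fingerprints.tsv"))
    p2 <- write_tsv(tests, file.path(out_dir, "fingerprint_tests.tsv"))
    outputs <- c(outputs, fingerprint = p2)
    results$fingerprint <- list(fingerprints = fp_long, tests = tests)
  }

  ## -- classify ------------------------------------------------------
  if ("classify" %in% stages) {
    say("stage: classify")
    queries <- list()
    outcome_list <- list()
    for (i in seq_along(rest)) {
      r <- rest[[i]]
      nuis <- nuisance_set(r$motion, run = r$run,
                           compartments = r$compartments)
      train <- build_training_set(r$run, r$parcellation, streams, nuis,
                                  highpass_s = config$highpass_s)
      qs <- lapply(cfg$seed_sites$name, function(nm) {
        list(subject = subjects[i], seed = nm,
             pattern = flatten_query(
               beta_maps[[paste(subjects[i], nm, sep = "_")]], train))
      })
      sw <- k_sweep(qs, train, k_range = config$k_range)
      outcome_list[[i]] <- sw$outcomes
    }
    outcomes <- do.call(rbind, outcome_list)
    dp <- stats::aggregate(label ~ seed, data = outcomes,
                           FUN = function(x) mean(x == "dorsal"))
    names(dp)[2] <- "dorsal_probability"
    cmp <- compare_outcomes(outcomes)
    p1 <- write_tsv(outcomes, file.path(out_dir, "classification_outcomes.tsv"))
    p2 <- write_tsv(dp, file.path(out_dir, "dorsal_probability.tsv"))
    outputs <- c(outputs, classify = p2)
    results$classify <- list(outcomes = outcomes, dorsal_probability = dp,
                             tests = cmp)
  }

  ## -- tract ---------------------------------------------------------
  if ("tract" %in% stages) {
    say("stage: tract")
    tc <- generate_tract_counts(cfg)
    st <- tract_strength(tc$records)
    ta <- tract_anova(st, with_hemisphere = TRUE)
    p1 <- write_tsv(st, file.path(out_dir, "tract_strengths.tsv"))
    p2 <- write_tsv(ta$anova, file.path(out_dir, "tract_anova.tsv"))
    outputs <- c(outputs, tract = p2)
    results$tract <- list(strengths = st, anova = ta)
  }

  ## -- manifest ------------------------------------------------------
  cfg_yaml <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config_to_list(config), cfg_yaml)
  manifest <- list(
    package_version = as.character(utils::packageVersion("streamconn")),
    config_hash = unname(tools::md5sum(cfg_yaml)),
    rng_seed = config$rng_seed,
    stages = as.list(outputs))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
  results$manifest <- manifest
  invisible(results)
}

# plain-list view of a config (for YAML serialization / hashing)
config_to_list <- function(config) {
  co <- config$cohort
  list(cohort = list(n_subjects = co$n_subjects,
                     grid_shape = co$grid_shape,
                     voxel_size_mm = co$voxel_size_mm,
                     tr_s = co$tr_s, n_volumes = co$n_volumes,
                     seed_sites = as.list(co$seed_sites),
                     parcel_loading = co$parcel_loading,
                     noise_sd = co$noise_sd, ar1_rho = co$ar1_rho,
                     motion_amplitude = co$motion_amplitude,
                     compartment_leak = co$compartment_leak,
                     seed_radius_mm = co$seed_radius_mm,
                     subject_jitter_vox = co$subject_jitter_vox,
                     rng_seed = co$rng_seed),
       sphere_radius_mm = config$sphere_radius_mm,
       search_radius_mm = config$search_radius_mm,
       highpass_s = config$highpass_s,
       smoothing_fwhm_mm = config$smoothing_fwhm_mm,
       n_perm = config$n_perm, k_range = config$k_range,
       boundary_n = config$boundary_n,
       motion_threshold_mm = config$motion_threshold_mm,
       n_targets = config$n_targets, rng_seed = config$rng_seed)
}
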