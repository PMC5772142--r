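#' First eigenvariate of an ROI timeseries
#'
#' Leading principal component of the time x voxel matrix after per-voxel
#' mean removal. The sign is fixed so that the mean voxel loading is
#' positive, and the component is scaled to the standard deviation of the
#' ROI mean timeseries, making the result deterministic and on the scale
#' of the underlying data.
#'
#' @param run A 4D [volume_image()] or a time x voxel matrix.
#' @param mask An [roi_mask()] (ignored when `run` is already a matrix).
#' @return A `seed_timeseries`: numeric vector of length `n_volumes` with
#'   attributes `method = "eigenvariate"` and `n_voxels`.
#' @export
first_eigenvariate <- function(run, mask = NULL) {
  Y <- if (inherits(run, "volume_image")) roi_timeseries(run, mask) else as.matrix(run)
  if (ncol(Y) < 1L) stop("empty ROI")
  Yc <- sweep(Y, 2, colMeans(Y))
  sds <- sqrt(colSums(Yc^2))
  if (all(sds < 1e-12)) stop("all ROI voxels are constant; zero variance")
  if (ncol(Yc) == 1L) {
    ts <- drop(Yc)
  } else {
    sv <- svd(Yc, nu = 1, nv = 1)
    ts <- drop(sv$u[, 1]) * sv$d[1]
    if (mean(sv$v[, 1]) < 0) ts <- -ts
  }
  target_sd <- stats::sd(rowMeans(Y))
  if (stats::sd(ts) > 0 && target_sd > 0) {
    ts <- ts / stats::sd(ts) * target_sd
  }
  structure(ts, method = "eigenvariate", n_voxels = ncol(Y),
            class = c("seed_timeseries", "numeric"))
}

#' Assemble the 15-column nuisance regressor set
#'
#' Six rigid-body motion parameters, their first-order temporal
#' differences, and three compartment signals (white matter, CSF,
#' out-of-brain means).
#'
#' @param motion n x 6 matrix/data frame of motion parameters.
#' @param run A 4D [volume_image()] from which compartment means are
#'   extracted, or `NULL` if `compartment_signals` is given directly.
#' @param compartments Named list of `roi_mask`s (`wm`, `csf`, `oob`), or
#'   `NULL` when `compartment_signals` supplies the columns.
#' @param compartment_signals Optional n x 3 matrix of precomputed
#'   compartment signals.
#' @return An n x 15 `nuisance_set` matrix.
#' @export
nuisance_set <- function(motion, run = NULL, compartments = NULL,
                         compartment_signals = NULL) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion table must have 6 columns")
  n <- nrow(motion)
  mdiff <- rbind(0, diff(motion))
  if (is.null(compartment_signals)) {
    if (is.null(run) || is.null(compartments)) {
      stop("either compartment_signals or run + compartments are required")
    }
    compartment_signals <- vapply(compartments[c("wm", "csf", "oob")],
                                  function(m) rowMeans(roi_timeseries(run, m)),
                                  numeric(n))
  }
  compartment_signals <- as.matrix(compartment_signals)
  if (ncol(compartment_signals) != 3L || nrow(compartment_signals) != n) {
    stop("compartment signals must be n_volumes x 3")
  }
  out <- cbind(motion, mdiff, compartment_signals)
  colnames(out) <- c(paste0("motion", 1:6), paste0("motion", 1:6, "_d"),
                     "wm", "csf", "oob")
  structure(out, class = c("nuisance_set", "matrix"))
}

#' Seed-based connectivity beta map
#'
#' Regresses every voxel's timeseries on the seed timeseries alongside the
#' 15 nuisance regressors, with high-pass filtering and pooled AR(1)
#' prewhitening as in [fit_glm()]. The returned map holds the seed
#' regressor's coefficient per voxel.
#'
#' @param run A 4D [volume_image()].
#' @param seed_ts A seed timeseries (e.g. [first_eigenvariate()]).
#' @param nuisance An [nuisance_set()] (or any numeric matrix of nuisance
#'   columns; may be `NULL` for a bare seed regression).
#' @param highpass_s High-pass cutoff (s), default 128.
#' @param seed_name,subject Labels attached to the result.
#' @return A `beta_map`: a 3D [volume_image()] with attributes `seed` and
#'   `subject`.
#' @export
seed_beta_map <- function(run, seed_ts, nuisance = NULL, highpass_s = 128,
                          seed_name = "seed", subject = NA) {
  X <- cbind(seed = as.numeric(seed_ts), nuisance)
  fit <- fit_glm(run, X, highpass_s = highpass_s)
  b <- fit$betas[1, ]
  img <- volume_image(array(b, fit$geometry$shape), fit$geometry$affine)
  attr(img, "seed") <- seed_name
  attr(img, "subject") <- subject
  class(img) <- c("beta_map", class(img))
  img
}

#' Average connectivity strength over stream target regions
#'
#' Mean beta over all voxels of all parcels belonging to each stream
#' (voxel-count-weighted across parcels), plus per-parcel means.
#'
#' @param beta A `beta_map` (3D [volume_image()]).
#' @param parc A [parcellation_volume()] on the same grid.
#' @param streams A `stream_table`.
#' @return A list with `streams` (data.frame `stream`, `value`, `n_voxels`)
#'   and `parcels` (data.frame `area_name`, `stream`, `value`, `n_voxels`).
#' @export
stream_strength <- function(beta, parc, streams) {
  stopifnot(inherits(beta, "volume_image"))
  if (!identical(dim(parc$label_data), dim(beta$data)[1:3])) {
    stop("parcellation grid does not match the beta map")
  }
  per <- lapply(seq_len(nrow(streams)), function(i) {
    m <- parcel_mask(parc, streams$area_name[i])
    v <- beta$data[mask_linear_index(m)]
    data.frame(area_name = streams$area_name[i], stream = streams$stream[i],
               value = mean(v), n_voxels = length(v))
  })
  parcels <- do.call(rbind, per)
  agg <- lapply(c("dorsal", "ventral"), function(s) {
    p <- parcels[parcels$stream == s, , drop = FALSE]
    nv <- sum(p$n_voxels)
    if (nv == 0L) stop("stream '", s, "' has zero voxels")
    data.frame(stream = s, value = sum(p$value * p$n_voxels) / nv,
               n_voxels = nv)
  })
  list(streams = do.call(rbind, agg), parcels = parcels)
}

#' Repeated-measures ANOVA on a long table of within-subject cells
#'
#' Fits a univariate repeated-measures ANOVA via `stats::aov` with an
#' `Error(subject/...)` stratum per within-subject term, for balanced
#' layouts where every subject contributes every factor cell.
#'
#' @param data Long data.frame with a `subject` column, a numeric `value`
#'   column, and the factor columns named in `within`.
#' @param within Character vector of within-subject factor names (crossed).
#' @param value,subject Column names for the response and subject id.
#' @return A data.frame of class `anova_result` with columns `effect`,
#'   `F`, `df1`, `df2`, `p`.
#' @export
repeated_anova <- function(data, within, value = "value",
                           subject = "subject") {
  data <- as.data.frame(data)
  for (w in c(within, subject)) data[[w]] <- factor(data[[w]])
  for (w in within) {
    if (nlevels(data[[w]]) < 2L) {
      stop("factor '", w, "' has fewer than 2 levels")
    }
  }
  # balance check: every subject must have every cell exactly once
  cells <- table(data[c(subject, within)])
  if (any(cells != 1L)) {
    miss <- which(cells == 0L, arr.ind = TRUE)
    stop("unbalanced within-subject layout (",
         sum(cells == 0L), " missing and ", sum(cells > 1L),
         " duplicated cells)")
  }
  rhs <- paste(within, collapse = " * ")
  fml <- stats::as.formula(paste0(value, " ~ ", rhs, " + Error(", subject,
                                  "/(", rhs, "))"))
  fit <- stats::aov(fml, data = data)
  sm <- summary(fit)
  out <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- rownames(tab)
    keep <- trimws(terms) != "Residuals"
    if (!any(keep)) next
    res_row <- which(!keep)
    for (i in which(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        effect = gsub(":", " x ", trimws(terms[i])),
        F = tab[i, "F value"],
        df1 = tab[i, "Df"],
        df2 = tab[res_row, "Df"],
        ss = tab[i, "Sum Sq"],
        p = tab[i, "Pr(>F)"])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("anova_result", "data.frame")
  res
}

#' Bonferroni-corrected 2 x 2 follow-up interactions
#'
#' For each pair of levels of `pair_factor`, runs the 2 x 2
#' repeated-measures interaction with `other_factor` and multiplies p by
#' the number of pairs (capped at 1).
#'
#' @param data Long data.frame as in [repeated_anova()].
#' @param pair_factor Factor whose level pairs are compared (e.g. seed).
#' @param other_factor The second factor of each 2 x 2 (e.g. stream).
#' @inheritParams repeated_anova
#' @return data.frame with columns `level_a`, `level_b`, `F`, `df1`,
#'   `df2`, `p`, `p_bonferroni`.
#' @export
pairwise_interactions <- function(data, pair_factor, other_factor,
                                  value = "value", subject = "subject") {
  lv <- unique(as.character(data[[pair_factor]]))
  pairs <- utils::combn(lv, 2)
  n_comp <- ncol(pairs)
  out <- lapply(seq_len(n_comp), function(i) {
    sub <- data[data[[pair_factor]] %in% pairs[, i], , drop = FALSE]
    a <- repeated_anova(sub, within = c(pair_factor, other_factor),
                        value = value, subject = subject)
    row <- a[a$effect == paste(pair_factor, "x", other_factor), , drop = FALSE]
    data.frame(level_a = pairs[1, i], level_b = pairs[2, i],
               F = row$F, df1 = row$df1, df2 = row$df2, p = row$p)
  })
  res <- do.call(rbind, out)
  res$p_bonferroni <- pmin(res$p * n_comp, 1)
  res
}

#' Screen subjects for excessive head motion
#'
#' Flags subjects whose maximum absolute translation exceeds the exclusion
#' threshold (default 3 mm).
#'
#' @param motion n x 6 motion matrix (first three columns translations,
#'   mm).
#' @param threshold_mm Exclusion threshold.
#' @return List with `pass` (logical) and `max_translation_mm`.
#' @export
screen_motion <- function(motion, threshold_mm = 3) {
  motion <- as.matrix(motion)
  mx <- max(abs(motion[, 1:3]))
  list(pass = mx <= threshold_mm, max_translation_mm = mx)
}

# 26-connectivity connected components over a logical 3D array.
# Returns an integer array of component labels (0 = background).
label_components_26 <- function(mask3d) {
  d <- dim(mask3d)
  labels <- array(0L, d)
  idx <- which(mask3d)
  if (!length(idx)) return(labels)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lin_off <- offs[, 1] + d[1] * offs[, 2] + d[1] * d[2] * offs[, 3]
  # precompute i/j/k for boundary checks
  comp <- 0L
  inmask <- array(FALSE, d); inmask[idx] <- TRUE
  for (s in idx) {
    if (labels[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    labels[s] <- comp
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      for (v in cur) {
        k0 <- (v - 1L) %/% (d[1] * d[2])
        r <- (v - 1L) %% (d[1] * d[2])
        j0 <- r %/% d[1]
        i0 <- r %% d[1]
        nb_i <- i0 + offs[, 1]; nb_j <- j0 + offs[, 2]; nb_k <- k0 + offs[, 3]
        ok <- nb_i >= 0 & nb_i < d[1] & nb_j >= 0 & nb_j < d[2] &
          nb_k >= 0 & nb_k < d[3]
        nb <- v + lin_off[ok]
        nb <- nb[inmask[nb] & labels[nb] == 0L]
        if (length(nb)) {
          labels[nb] <- comp
          queue <- c(queue, nb)
        }
      }
    }
  }
  labels
}

#' Group-level map with permutation-based cluster FWE inference
#'
#' One-sample (or paired-difference) t test across subjects at every
#' voxel; clusters of contiguous voxels (26-connectivity) exceeding the
#' cluster-forming threshold are evaluated by cluster mass against a
#' sign-flip permutation distribution of the maximum cluster mass,
#' yielding family-wise-error-corrected p values. Positive and negative
#' clusters are assessed against the same two-sided null.
#'
#' @param betas List of 3D `beta_map`s / [volume_image()]s on one grid
#'   (for a paired contrast, pass the per-subject difference maps).
#' @param cluster_p Cluster-forming (uncorrected, two-sided) p threshold.
#' @param n_perm Number of sign-flip permutations.
#' @param rng_seed Integer seed for the permutation stream.
#' @return List with `tmap` (a [volume_image()]) and `clusters`
#'   (data.frame: `cluster`, `sign`, `n_voxels`, `mass`, `peak_t`,
#'   `peak_mm` columns, `p_fwe`).
#' @export
group_map <- function(betas, cluster_p = 0.001, n_perm = 1000,
                      rng_seed = 1L) {
  n <- length(betas)
  if (n < 2L) stop("at least 2 subjects are required")
  d <- dim(betas[[1]]$data)
  M <- vapply(betas, function(b) as.numeric(b$data), numeric(prod(d)))
  M <- t(M)   # subjects x voxels
  tstat <- function(S) {
    mu <- colMeans(S)
    se <- sqrt(apply(S, 2, stats::var) / nrow(S))
    ifelse(se > 0, mu / se, 0)
  }
  tv <- tstat(M)
  thr <- stats::qt(1 - cluster_p / 2, df = n - 1)
  cluster_masses <- function(tvec) {
    out <- list(pos = numeric(0), neg = numeric(0),
                pos_lab = NULL, neg_lab = NULL)
    for (sgn in c(1, -1)) {
      mask <- array(sgn * tvec > thr, d)
      lab <- label_components_26(mask)
      if (max(lab) > 0) {
        mass <- vapply(seq_len(max(lab)),
                       function(cc) sum(abs(tvec[lab == cc])), numeric(1))
        if (sgn > 0) { out$pos <- mass; out$pos_lab <- lab }
        else { out$neg <- mass; out$neg_lab <- lab }
      }
    }
    out
  }
  obs <- cluster_masses(tv)
  set.seed(as.integer(rng_seed))
  max_null <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    tp <- tstat(M * flips)
    cm <- cluster_masses(tp)
    max_null[p] <- max(c(cm$pos, cm$neg, 0))
  }
  rows <- list()
  add_rows <- function(masses, lab, sgn) {
    for (cc in seq_along(masses)) {
      vox <- which(lab == cc)
      pk <- vox[which.max(abs(tv[vox]))]
      ijk <- arrayInd(pk, d) - 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        sign = if (sgn > 0) "positive" else "negative",
        n_voxels = length(vox), mass = masses[cc],
        peak_t = tv[pk],
        peak_x = voxel_to_world(ijk, betas[[1]]$affine)[1],
        peak_y = voxel_to_world(ijk, betas[[1]]$affine)[2],
        peak_z = voxel_to_world(ijk, betas[[1]]$affine)[3],
        p_fwe = (1 + sum(max_null >= masses[cc])) / (1 + n_perm))
    }
  }
  if (length(obs$pos)) add_rows(obs$pos, obs$pos_lab, 1)
  if (length(obs$neg)) add_rows(obs$neg, obs$neg_lab, -1)
  clusters <- if (length(rows)) {
    out <- do.call(rbind, rows)
    out <- out[order(out$p_fwe, -out$mass), , drop = FALSE]
    out$cluster <- seq_len(nrow(out))
    rownames(out) <- NULL
    out[, c("cluster", "sign", "n_voxels", "mass", "peak_t",
            "peak_x", "peak_y", "peak_z", "p_fwe")]
  } else {
    data.frame(cluster = integer(0), sign = character(0),
               n_voxels = integer(0), mass = numeric(0), peak_t = numeric(0),
               peak_x = numeric(0), peak_y = numeric(0), peak_z = numeric(0),
               p_fwe = numeric(0))
  }
  list(tmap = volume_image(array(tv, d), betas[[1]]$affine),
       clusters = clusters)
}
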