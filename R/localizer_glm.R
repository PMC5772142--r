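#' Canonical double-gamma haemodynamic response function
#'
#' The conventional two-gamma shape: response peak at 6 s, undershoot at
#' 16 s, peak:undershoot amplitude ratio 6, unit dispersion. Evaluated on
#' an arbitrary time grid in seconds.
#'
#' @param t Time points in seconds (>= 0 contributes; t < 0 returns 0).
#' @param peak_delay,undershoot_delay Gamma shape parameters (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return Numeric vector of HRF values (unit peak-area convention:
#'   normalized so that the function sums to 1 on the evaluation grid is
#'   NOT applied; the raw double-gamma density difference is returned).
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    stats::dgamma(t, shape = undershoot_delay, rate = 1) / ratio
  h[t < 0] <- 0
  h
}

#' Block design description
#'
#' @param conditions Data frame with columns `condition`, `onset` (s),
#'   `duration` (s).
#' @param nuisance_events Optional numeric vector of event onsets (s) for a
#'   punctate regressor of no interest (e.g. button presses).
#' @param run_duration_s Total run duration in seconds.
#' @return A `block_design`.
#' @export
block_design <- function(conditions, nuisance_events = numeric(0),
                         run_duration_s) {
  stopifnot(all(c("condition", "onset", "duration") %in% names(conditions)))
  if (nrow(conditions) > 0) {
    if (any(conditions$duration <= 0)) stop("block durations must be > 0")
    if (any(conditions$onset < 0) ||
        any(conditions$onset + conditions$duration > run_duration_s + 1e-9)) {
      stop("blocks must lie within the run duration")
    }
    # overlapping blocks of the same condition are a design error
    for (cc in unique(conditions$condition)) {
      b <- conditions[conditions$condition == cc, , drop = FALSE]
      b <- b[order(b$onset), , drop = FALSE]
      if (nrow(b) > 1 &&
          any(b$onset[-1] < (b$onset + b$duration)[-nrow(b)] - 1e-9)) {
        stop("overlapping blocks in condition '", cc, "'")
      }
    }
  }
  structure(list(conditions = conditions,
                 nuisance_events = as.numeric(nuisance_events),
                 run_duration_s = run_duration_s),
            class = "block_design")
}

# Convolve a stimulus function sampled at microtime resolution with the
# canonical HRF and (optionally) its temporal derivative, then sample at
# volume acquisition times. 16x microtime upsampling relative to TR.
convolve_regressor <- function(onsets, durations, tr_s, n_volumes,
                               upsample = 16L, derivative = FALSE) {
  dt <- tr_s / upsample
  n_fine <- n_volumes * upsample
  stim <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1L
    b <- min(ceiling((onsets[i] + durations[i]) / dt), n_fine)
    if (a <= n_fine && b >= a) stim[a:b] <- 1
  }
  hrf_t <- seq(0, 32, by = dt)
  h <- canonical_hrf(hrf_t) * dt
  conv <- stats::convolve(stim, rev(h), type = "open")[seq_len(n_fine)]
  if (derivative) {
    hd <- c(diff(h), 0) / dt
    conv <- stats::convolve(stim, rev(hd), type = "open")[seq_len(n_fine)]
  }
  conv[seq(1L, n_fine, by = upsample)]
}

#' Build a block-design GLM design matrix
#'
#' Task regressors are square waves over the block durations convolved
#' with the canonical HRF and its temporal derivative (one pair per
#' condition), plus a punctate button-press regressor, the six rigid-body
#' motion parameters and their first-order temporal differences. The
#' intercept and drift terms are handled inside [fit_glm()].
#'
#' @param design A [block_design()].
#' @param tr_s Repetition time (s).
#' @param n_volumes Number of volumes.
#' @param motion Data frame or matrix of 6 motion parameters, one row per
#'   volume, or `NULL` to omit motion regressors.
#' @return A `design_matrix`: numeric matrix with named columns and
#'   attribute `task_columns` (names of the HRF main-effect columns).
#' @export
build_design <- function(design, tr_s, n_volumes, motion = NULL) {
  stopifnot(inherits(design, "block_design"))
  cols <- list()
  task_cols <- character(0)
  conds <- design$conditions
  if (nrow(conds) == 0L) {
    warning("design has no task blocks; nuisance-only design matrix")
  }
  for (cc in unique(conds$condition)) {
    b <- conds[conds$condition == cc, , drop = FALSE]
    main <- convolve_regressor(b$onset, b$duration, tr_s, n_volumes)
    deriv <- convolve_regressor(b$onset, b$duration, tr_s, n_volumes,
                                derivative = TRUE)
    cols[[cc]] <- main
    cols[[paste0(cc, "_deriv")]] <- deriv
    task_cols <- c(task_cols, cc)
    # a block spanning the run is constant once the convolution transient
    # has passed, leaving the column collinear with the intercept
    post <- main[-seq_len(min(ceiling(32 / tr_s), n_volumes - 2L))]
    if (stats::sd(main) < 1e-10 ||
        (length(post) > 2 && stats::sd(post) < 1e-10)) {
      warning("task column '", cc, "' is (near) constant; ",
              "contrast estimation will be ill-posed")
    }
  }
  if (length(design$nuisance_events)) {
    cols[["button"]] <- convolve_regressor(design$nuisance_events,
                                           rep(0.1, length(design$nuisance_events)),
                                           tr_s, n_volumes)
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_volumes) {
      stop("motion table has ", nrow(motion), " rows; expected ", n_volumes)
    }
    if (ncol(motion) != 6L) stop("motion table must have 6 columns")
    mdiff <- rbind(0, diff(motion))
    colnames(motion) <- paste0("motion", 1:6)
    colnames(mdiff) <- paste0("motion", 1:6, "_d")
    for (j in 1:6) cols[[colnames(motion)[j]]] <- motion[, j]
    for (j in 1:6) cols[[colnames(mdiff)[j]]] <- mdiff[, j]
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n_volumes, ncol = 0)
  structure(X, task_columns = task_cols, class = c("design_matrix", "matrix"))
}

# Discrete-cosine drift basis with periods longer than cutoff_s, excluding
# the constant term (the intercept is added separately). Columns are
# orthonormal.
dct_basis <- function(n, tr_s, cutoff_s) {
  if (is.null(cutoff_s) || !is.finite(cutoff_s) || cutoff_s <= 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  k_max <- floor(2 * n * tr_s / cutoff_s)
  if (k_max < 1L) return(matrix(numeric(0), nrow = n, ncol = 0))
  t0 <- seq_len(n) - 1L
  B <- vapply(seq_len(k_max),
              function(k) cos(pi * k * (2 * t0 + 1) / (2 * n)),
              numeric(n))
  B <- matrix(B, nrow = n)
  sweep(B, 2, sqrt(colSums(B^2)), "/")
}

# Core mass-univariate GLM: intercept + drift handled internally, pooled
# AR(1) prewhitening. Y is time x voxel. Returns coefficient matrix for
# the user columns of X plus the pieces needed for t maps.
glm_engine <- function(Y, X, tr_s, highpass_s = 128, ar1 = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("design and data disagree on the number of volumes")
  p_user <- ncol(X)
  D <- dct_basis(n, tr_s, highpass_s)
  Xf <- cbind(X, intercept = 1, D)
  if (ncol(D)) colnames(Xf)[(p_user + 2):ncol(Xf)] <- paste0("dct", seq_len(ncol(D)))
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    dropped <- colnames(Xf)[qrX$pivot[(qrX$rank + 1):ncol(Xf)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y)
  resid <- Y - Xf %*% beta
  rho <- 0
  if (ar1 && n > 2) {
    num <- sum(resid[-1, ] * resid[-n, ])
    den <- sum(resid^2)
    rho <- if (den > 0) num / den else 0
    # projecting out p regression/drift columns deflates the residual lag-1
    # autocorrelation by roughly (1 + rho) * p / n; undo that bias
    rho <- rho + (1 + rho) * ncol(Xf) / n
    rho <- max(min(rho, 0.99), -0.99)
    if (abs(rho) > 1e-8) {
      W1 <- sqrt(1 - rho^2)
      Yw <- rbind(Y[1, , drop = FALSE] * W1,
                  Y[-1, , drop = FALSE] - rho * Y[-n, , drop = FALSE])
      Xw <- rbind(Xf[1, , drop = FALSE] * W1,
                  Xf[-1, , drop = FALSE] - rho * Xf[-n, , drop = FALSE])
      qrX <- qr(Xw)
      if (qrX$rank < ncol(Xw)) {
        stop("design matrix became rank deficient after prewhitening")
      }
      beta <- qr.coef(qrX, Yw)
      resid <- Yw - Xw %*% beta
      Xf <- Xw
    }
  }
  dof <- n - ncol(Xf)
  if (dof <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(resid^2) / dof
  XtXinv <- chol2inv(chol(crossprod(Xf)))
  list(betas = beta[seq_len(p_user), , drop = FALSE],
       all_betas = beta, sigma2 = sigma2, dof = dof, rho = rho,
       XtXinv = XtXinv, p_user = p_user, n_col = ncol(Xf),
       colnames = colnames(Xf))
}

#' Fit a mass-univariate GLM to a 4D run
#'
#' High-pass filtering uses a discrete-cosine drift basis (periods longer
#' than `highpass_s`) estimated jointly with the design; temporal
#' autocorrelation is modelled as a first-order autoregressive process with
#' a single pooled coefficient estimated from the OLS residuals, after
#' which data and design are prewhitened and coefficients re-estimated.
#'
#' @param run A 4D [volume_image()] (or a time x voxel matrix with
#'   `tr_s` supplied).
#' @param X A [build_design()] matrix (columns of interest + nuisance).
#' @param highpass_s High-pass cutoff in seconds (default 128).
#' @param tr_s Repetition time; taken from `run` when it is a
#'   `volume_image`.
#' @return A `glm_fit` with per-voxel `betas` (columns of `X` only),
#'   `sigma2`, pooled `ar1_rho`, residual `dof`, and grid geometry when
#'   fitted to a volume.
#' @export
fit_glm <- function(run, X, highpass_s = 128, tr_s = NULL) {
  if (inherits(run, "volume_image")) {
    if (!is_4d(run)) stop("a 4D run is required")
    d <- dim(run$data)
    Y <- matrix(run$data, nrow = prod(d[1:3]), ncol = d[4])
    Y <- t(Y)
    tr_s <- tr_s %||% run$tr_s
    geom <- list(shape = d[1:3], affine = run$affine)
  } else {
    Y <- as.matrix(run)
    geom <- NULL
  }
  if (is.null(tr_s)) stop("tr_s is required")
  eng <- glm_engine(Y, X, tr_s, highpass_s = highpass_s)
  structure(c(eng, list(geometry = geom, tr_s = tr_s)), class = "glm_fit")
}

#' Compute a voxelwise t map for a linear contrast
#'
#' @param fit A [fit_glm()] result fitted to a `volume_image`.
#' @param weights Contrast weights over the user design columns (recycled
#'   with zeros for intercept/drift columns).
#' @return A 3D [volume_image()] of t statistics (when the fit has grid
#'   geometry) or a numeric vector otherwise. Voxels with zero residual
#'   variance receive signed `Inf` (0 for a zero contrast estimate).
#' @export
contrast_map <- function(fit, weights) {
  stopifnot(inherits(fit, "glm_fit"))
  if (length(weights) != fit$p_user) {
    stop("contrast weights must have length ", fit$p_user)
  }
  cvec <- c(weights, rep(0, fit$n_col - fit$p_user))
  est <- drop(crossprod(cvec, fit$all_betas))
  cvar <- drop(t(cvec) %*% fit$XtXinv %*% cvec)
  se <- sqrt(fit$sigma2 * cvar)
  tmap <- est / se
  zero_var <- which(se == 0 | !is.finite(se))
  if (length(zero_var)) {
    tmap[zero_var] <- sign(est[zero_var]) * Inf
    tmap[zero_var][est[zero_var] == 0] <- 0
    message(length(zero_var), " voxel(s) with zero residual variance; ",
            "t set to signed infinity")
  }
  if (!is.null(fit$geometry)) {
    volume_image(array(tmap, fit$geometry$shape), fit$geometry$affine)
  } else tmap
}

#' Combine multi-echo EPI volumes into one weighted timeseries
#'
#' Per voxel, echo weights are proportional to the echo time multiplied by
#' the temporal signal-to-noise ratio estimated from the first `n_est`
#' volumes, normalized to sum to one, and applied to the whole timeseries.
#' Voxels whose estimation-window variance is zero in any echo fall back to
#' TE-proportional weights.
#'
#' @param echoes List of 4D [volume_image()]s on a common grid.
#' @param te_ms Echo times in milliseconds, one per echo.
#' @param n_est Number of leading volumes used to estimate tSNR.
#' @return A 4D [volume_image()] of the weighted combination.
#' @export
combine_echoes <- function(echoes, te_ms, n_est = 30) {
  if (length(echoes) < 2L) stop("at least 2 echoes are required")
  if (length(te_ms) != length(echoes)) stop("one TE per echo is required")
  d <- dim(echoes[[1]]$data)
  for (e in echoes) {
    if (!identical(dim(e$data), d)) stop("echoes must share one grid")
  }
  n_est <- min(n_est, d[4])
  nvox <- prod(d[1:3])
  flat <- lapply(echoes, function(e) matrix(e$data, nrow = nvox, ncol = d[4]))
  tsnr <- vapply(flat, function(m) {
    w <- m[, seq_len(n_est), drop = FALSE]
    mu <- rowMeans(w)
    s <- sqrt(rowSums((w - mu)^2) / (n_est - 1))
    ifelse(s > 0, abs(mu) / s, NA_real_)
  }, numeric(nvox))
  W <- sweep(matrix(tsnr, nrow = nvox), 2, te_ms, "*")
  fallback <- !stats::complete.cases(W)
  if (any(fallback)) {
    message(sum(fallback), " voxel(s) with zero-variance estimation window; ",
            "TE-proportional weights used")
    W[fallback, ] <- matrix(te_ms, nrow = sum(fallback),
                            ncol = length(te_ms), byrow = TRUE)
  }
  W <- W / rowSums(W)
  out <- matrix(0, nrow = nvox, ncol = d[4])
  for (j in seq_along(flat)) out <- out + W[, j] * flat[[j]]
  volume_image(array(out, d), echoes[[1]]$affine, tr_s = echoes[[1]]$tr_s)
}

#' Smooth a 3D map with an isotropic Gaussian kernel
#'
#' Separable convolution with a Gaussian of the given full width at half
#' maximum in millimetres; voxel sizes are taken from the affine.
#'
#' @param img A 3D [volume_image()].
#' @param fwhm_mm Kernel FWHM in mm (0 returns the input unchanged).
#' @return A smoothed [volume_image()].
#' @export
gaussian_smooth <- function(img, fwhm_mm = 6) {
  stopifnot(inherits(img, "volume_image"))
  if (fwhm_mm <= 0) return(img)
  d <- dim(img$data)
  stopifnot(length(d) == 3L)
  vox <- sqrt(colSums(img$affine[1:3, 1:3]^2))
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox   # sigma in voxels per axis
  x <- img$data
  for (ax in 1:3) {
    r <- max(1L, ceiling(3 * sig[ax]))
    k <- stats::dnorm(seq(-r, r), sd = sig[ax])
    k <- k / sum(k)
    x <- apply_along(x, ax, function(v) conv_same_reflect(v, k))
  }
  volume_image(x, img$affine)
}

# 1D convolution with reflection padding, output length preserved
conv_same_reflect <- function(v, k) {
  r <- (length(k) - 1L) / 2L
  n <- length(v)
  pad <- c(v[pmin(pmax(r:1, 1L), n)], v, v[pmin(pmax(n - 1:r + 0L, 1L), n)])
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

apply_along <- function(x, axis, f) {
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[axis])
  m <- apply(m, 2, f)
  xp <- array(m, d[perm])
  aperm(xp, order(perm))
}

#' Locate the peak of a statistic map within a spherical search region
#'
#' Returns the world coordinate of the maximum statistic inside the search
#' sphere. Ties are broken deterministically by smallest voxel index in
#' lexicographic order.
#'
#' @param tmap A 3D statistic [volume_image()].
#' @param search An [roi_spec()] giving the search sphere (centre and
#'   radius in mm).
#' @param name,hemisphere Labels carried into the result.
#' @return A `seed_location`: list with `name`, `hemisphere`, `coord_mm`,
#'   `peak_stat`, `voxel_index`.
#' @export
localize_seed <- function(tmap, search, name = search$name,
                          hemisphere = NA_character_) {
  stopifnot(inherits(tmap, "volume_image"))
  mask <- build_sphere_roi(search, tmap$affine, dim(tmap$data))
  vals <- tmap$data[mask_linear_index(mask)]
  if (all(is.na(vals))) stop("all statistics are NA inside the search region")
  best <- which(vals == max(vals, na.rm = TRUE))[1]  # indices already lex-sorted
  idx <- mask$voxel_indices[best, ]
  structure(list(name = name, hemisphere = hemisphere,
                 coord_mm = drop(voxel_to_world(rbind(idx), tmap$affine)),
                 peak_stat = vals[best], voxel_index = idx),
            class = "seed_location")
}

#' @export
print.seed_location <- function(x, ...) {
  cat(sprintf("<seed_location> %s [%s]: (%.1f, %.1f, %.1f) mm, stat %.2f\n",
              x$name, x$hemisphere, x$coord_mm[1], x$coord_mm[2],
              x$coord_mm[3], x$peak_stat))
  invisible(x)
}
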