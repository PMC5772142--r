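make_echo <- function(data, g, tr = 2) volume_image(data, g$affine, tr_s = tr)

test_that("echo combination weights are TE x tSNR, normalized to sum 1", {
  set.seed(10)
  g <- test_grid(shape = c(4, 4, 3))
  d <- c(4, 4, 3, 40)
  base <- array(rnorm(prod(d), mean = 100, sd = 1), d)
  # identical echoes: the combination equals each input
  comb <- combine_echoes(list(make_echo(base, g), make_echo(base, g)),
                         te_ms = c(10, 30))
  expect_equal(comb$data, base)
  # equal tSNR across echoes: weights proportional to TE (direct formula)
  e2 <- base * 2   # mean and sd both double; tSNR identical
  comb2 <- combine_echoes(list(make_echo(base, g), make_echo(e2, g)),
                          te_ms = c(10, 30))
  w <- c(10, 30) / 40
  expect_equal(comb2$data, w[1] * base + w[2] * e2, tolerance = 1e-12)
  expect_error(combine_echoes(list(make_echo(base, g)), te_ms = 10),
               "at least 2")
})

test_that("zero-variance voxels fall back to TE-proportional weights", {
  g <- test_grid(shape = c(2, 2, 2))
  d <- c(2, 2, 2, 35)
  set.seed(11)
  a <- array(rnorm(prod(d), 50), d)
  b <- array(rnorm(prod(d), 50), d)
  a[1, 1, 1, ] <- 7   # constant in the estimation window
  expect_message(combine_echoes(list(make_echo(a, g), make_echo(b, g)),
                                te_ms = c(10, 30)),
                 "TE-proportional")
})

test_that("the design matrix has the documented columns", {
  set.seed(12)
  n <- 150; tr <- 2
  bd <- block_design(
    data.frame(condition = rep(c("bodies", "objects", "scrambled"), 3),
               onset = seq(10, 235, by = 26), duration = 16),
    nuisance_events = c(20, 80, 140),
    run_duration_s = n * tr)
  X <- build_design(bd, tr, n, motion = matrix(rnorm(n * 6, sd = .1), n, 6))
  expect_equal(ncol(X), 3 * 2 + 1 + 6 + 6)
  expect_setequal(attr(X, "task_columns"), c("bodies", "objects", "scrambled"))
  expect_error(build_design(bd, tr, n, motion = matrix(0, 10, 6)),
               "rows")
  expect_warning(build_design(block_design(
    data.frame(condition = character(0), onset = numeric(0),
               duration = numeric(0)), run_duration_s = n * tr), tr, n),
    "no task blocks")
})

test_that("a whole-run block yields a near-constant column with a warning", {
  n <- 100; tr <- 2
  bd <- block_design(data.frame(condition = "a", onset = 0, duration = n * tr),
                     run_duration_s = n * tr)
  expect_warning(build_design(bd, tr, n), "constant")
})

test_that("the convolved column peaks where direct convolution says", {
  n <- 150; tr <- 2
  bd <- block_design(data.frame(condition = "a", onset = 40, duration = 20),
                     run_duration_s = n * tr)
  X <- build_design(bd, tr, n)
  # direct convolution oracle at fine resolution
  dt <- 0.125
  tfine <- seq(0, n * tr - dt, by = dt)
  stim <- as.numeric(tfine >= 40 & tfine < 60)
  h <- canonical_hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(stim, rev(h), type = "open")[seq_along(tfine)]
  peak_oracle <- tfine[which.max(conv)]
  peak_col <- (which.max(X[, "a"]) - 1) * tr
  expect_lt(abs(peak_col - peak_oracle), tr + 1e-9)
  # and the peak lags the onset by roughly the HRF delay plus part of the block
  expect_gt(peak_col, 40 + 4)
  expect_lt(peak_col, 40 + 20)
})

test_that("noiseless GLM recovery is exact", {
  set.seed(13)
  n <- 120; tr <- 2
  bd <- block_design(data.frame(condition = c("a", "b"), onset = c(20, 120),
                                duration = 16), run_duration_s = n * tr)
  X <- build_design(bd, tr, n, motion = matrix(rnorm(n * 6, sd = .1), n, 6))
  beta <- rnorm(ncol(X))
  y <- X %*% beta + 5
  fit <- fit_glm(cbind(y), X, tr_s = tr)
  expect_lt(max(abs(fit$betas - beta)), 1e-8)
})

test_that("high-pass filtering removes slow drift and is idempotent", {
  set.seed(14)
  n <- 200; tr <- 2
  bd <- block_design(data.frame(condition = "a", onset = seq(20, 360, 60),
                                duration = 16), run_duration_s = n * tr)
  X <- build_design(bd, tr, n)
  t_s <- (seq_len(n) - 1) * tr
  drift <- sin(2 * pi * t_s / 300)   # 300 s period, above the 128 s cutoff
  fit <- fit_glm(cbind(drift), X, tr_s = tr, highpass_s = 128)
  expect_lt(abs(fit$betas[1, 1]), 0.02)
  # idempotence of the projection: residualizing twice = once
  D <- streamconn:::dct_basis(n, tr, 128)
  P <- diag(n) - D %*% t(D)
  y <- rnorm(n)
  expect_equal(P %*% (P %*% y), P %*% y, tolerance = 1e-12)
})

test_that("pooled AR(1) estimation recovers the planted coefficient", {
  set.seed(15)
  n <- 500; tr <- 2
  bd <- block_design(data.frame(condition = "a", onset = seq(20, 900, 60),
                                duration = 16), run_duration_s = n * tr)
  X <- build_design(bd, tr, n)
  rhos <- replicate(200, {
    y <- as.numeric(arima.sim(list(ar = 0.4), n))
    fit_glm(cbind(y), X, tr_s = tr)$rho
  })
  expect_lt(abs(mean(rhos) - 0.4), 0.05)
})

test_that("rank-deficient designs raise an error naming the problem", {
  n <- 80
  X <- cbind(a = rnorm(n))
  X <- cbind(X, b = X[, "a"])
  expect_error(fit_glm(cbind(rnorm(n)), X, tr_s = 2), "rank deficient")
})

test_that("contrast t statistics are calibrated under the null", {
  set.seed(16)
  n <- 100; tr <- 2
  bd <- block_design(data.frame(condition = c("a", "b"),
                                onset = c(20, 110), duration = 16),
                     run_duration_s = n * tr)
  X <- build_design(bd, tr, n)
  Y <- matrix(rnorm(n * 2000), n, 2000)
  fit <- fit_glm(Y, X, tr_s = tr)
  w <- numeric(ncol(X)); w[colnames(X) == "a"] <- 1; w[colnames(X) == "b"] <- -1
  tv <- contrast_map(fit, w)
  crit <- qt(0.975, df = fit$dof)
  expect_lt(abs(mean(abs(tv) > crit) - 0.05), 0.015)
  # zero-weight contrast gives an all-zero map
  expect_true(all(contrast_map(fit, numeric(ncol(X))) == 0))
})

test_that("t statistics on white noise follow the Student-t distribution", {
  set.seed(17)
  n <- 100; tr <- 2
  bd <- block_design(data.frame(condition = "a", onset = seq(10, 170, 40),
                                duration = 16), run_duration_s = n * tr)
  X <- build_design(bd, tr, n)
  Y <- matrix(rnorm(n * 1000), n, 1000)
  fit <- fit_glm(Y, X, tr_s = tr)
  w <- numeric(ncol(X)); w[1] <- 1
  tv <- as.numeric(contrast_map(fit, w))
  ks <- suppressWarnings(ks.test(tv, pt, df = fit$dof))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("seed localization breaks ties deterministically and handles r = 0", {
  g <- test_grid(shape = c(11, 11, 11))
  flat <- volume_image(array(1, c(11, 11, 11)), g$affine)
  sl <- localize_seed(flat, roi_spec("s", c(0, 0, 0), 6))
  # lexicographically first voxel of the sphere
  m <- build_sphere_roi(roi_spec("s", c(0, 0, 0), 6), g$affine, g$shape)
  expect_equal(sl$voxel_index, m$voxel_indices[1, ])
  sl0 <- localize_seed(flat, roi_spec("s", c(2, -2, 4), 0))
  expect_equal(unname(sl0$coord_mm), c(2, -2, 4))
  nas <- volume_image(array(NA_real_, c(11, 11, 11)), g$affine)
  expect_error(localize_seed(nas, roi_spec("s", c(0, 0, 0), 4)), "NA")
})

test_that("planted seed sites are recovered across a synthetic cohort", {
  cfg <- synthetic_cohort_config(n_subjects = 6, grid_shape = c(18, 18, 14),
                                 n_volumes = 120, rng_seed = 18)
  hits <- 0; tot <- 0
  for (s in 1:3) {
    loc <- generate_localizer_run(cfg, s)
    X <- build_design(block_design(loc$events,
                                   run_duration_s = cfg$n_volumes * cfg$tr_s),
                      cfg$tr_s, cfg$n_volumes, motion = loc$motion)
    fit <- fit_glm(loc$run, X)
    cn <- colnames(X)
    for (nm in c("EBA", "FBA", "LOC")) {
      w <- numeric(length(cn))
      if (nm %in% c("EBA", "FBA")) {
        w[cn == "bodies"] <- 1; w[cn == "objects"] <- -1
      } else {
        w[cn == "objects"] <- 1; w[cn == "scrambled"] <- -1
      }
      tmap <- contrast_map(fit, w)
      site <- cfg$seed_sites[cfg$seed_sites$name == nm, ]
      sl <- localize_seed(tmap, roi_spec(nm, c(site$x, site$y, site$z), 10))
      truth <- loc$ground_truth$seed_sites
      tv <- unlist(truth[truth$name == nm, c("x", "y", "z")])
      tot <- tot + 1
      if (sqrt(sum((sl$coord_mm - tv)^2)) <=
          cfg$voxel_size_mm * sqrt(3) + 1e-9) hits <- hits + 1
    }
  }
  expect_gte(hits / tot, 8 / 9)
})

test_that("gaussian smoothing preserves the mean and spreads a point source", {
  g <- test_grid(shape = c(15, 15, 15))
  a <- array(0, c(15, 15, 15)); a[8, 8, 8] <- 1
  sm <- gaussian_smooth(volume_image(a, g$affine), fwhm_mm = 6)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
  expect_lt(max(sm$data), 1)
  expect_equal(which.max(sm$data), which.max(a))
  expect_identical(gaussian_smooth(volume_image(a, g$affine), 0)$data, a)
})
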