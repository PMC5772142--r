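test_that("first eigenvariate handles rank-1, single-voxel and mixed ROIs", {
  set.seed(20)
  n <- 150
  lat <- as.numeric(arima.sim(list(ar = 0.3), n))
  # all voxels share one timeseries: output correlates 1 with it
  Y1 <- outer(lat, rep(1, 8))
  ev <- first_eigenvariate(Y1)
  expect_equal(abs(cor(ev, lat)), 1, tolerance = 1e-10)
  # scaled to the sd of the ROI mean timeseries
  expect_equal(sd(ev), sd(rowMeans(Y1)), tolerance = 1e-10)
  # single voxel: the demeaned series itself
  y <- rnorm(n)
  ev1 <- first_eigenvariate(cbind(y))
  expect_equal(as.numeric(ev1), y - mean(y), tolerance = 1e-10)
  expect_error(first_eigenvariate(matrix(3, n, 4)), "constant")
})

test_that("eigenvariate of anti-correlated groups matches an SVD oracle", {
  set.seed(21)
  n <- 300
  base <- rnorm(n)
  Y <- cbind(outer(base, rep(1, 6)), outer(-base, rep(1, 4))) +
    matrix(rnorm(n * 10, sd = 0.3), n, 10)
  ev <- first_eigenvariate(Y)
  # majority group (6 voxels) has positive mean loading: positive correlation
  expect_gt(cor(ev, base), 0.9)
  # direct eigendecomposition oracle
  Yc <- sweep(Y, 2, colMeans(Y))
  pc <- eigen(crossprod(Yc))$vectors[, 1]
  oracle <- drop(Yc %*% pc)
  if (mean(pc) < 0) oracle <- -oracle
  expect_equal(abs(drop(cor(ev, oracle))), 1, tolerance = 1e-8)
})

test_that("seed beta maps recover exact coefficients without noise", {
  set.seed(22)
  g <- test_grid(shape = c(6, 6, 4))
  n <- 80
  seed_ts <- as.numeric(scale(rnorm(n)))
  nuis <- matrix(rnorm(n * 15), n, 15)
  a <- runif(prod(g$shape), -1, 1)
  flat <- outer(a, seed_ts) + matrix(rnorm(15 * prod(g$shape)), ncol = 15) %*%
    t(nuis)   # voxel x time
  run <- volume_image(array(flat, c(g$shape, n)), g$affine, tr_s = 2)
  bm <- seed_beta_map(run, seed_ts, nuis)
  expect_lt(max(abs(as.numeric(bm$data) - a)), 1e-8)
})

test_that("betas are invariant to adding nuisance signal to the data", {
  set.seed(23)
  g <- test_grid(shape = c(5, 5, 4))
  n <- 80
  seed_ts <- rnorm(n)
  nuis <- matrix(rnorm(n * 15), n, 15)
  a <- runif(prod(g$shape), -1, 1)
  flat <- outer(a, seed_ts)
  run1 <- volume_image(array(flat, c(g$shape, n)), g$affine, tr_s = 2)
  contam <- flat + outer(rep(1, prod(g$shape)),
                         drop(nuis %*% runif(15, -2, 2)))
  run2 <- volume_image(array(contam, c(g$shape, n)), g$affine, tr_s = 2)
  b1 <- seed_beta_map(run1, seed_ts, nuis)
  b2 <- seed_beta_map(run2, seed_ts, nuis)
  expect_lt(max(abs(b1$data - b2$data)), 1e-8)
  # a voxel carrying pure compartment signal has seed beta ~ 0
  expect_lt(max(abs(b2$data - array(a, dim(b2$data)))), 1e-8)
})

test_that("planted couplings are recovered by the full seed-map chain", {
  # seed site with unit dorsal loading; dorsal parcels at loading 0.6:
  # the mean recovered beta over dorsal parcels approximates 0.6
  cfg <- synthetic_cohort_config(
    n_subjects = 5, grid_shape = c(12, 12, 10), n_volumes = 500,
    seed_sites = data.frame(name = "S", x = 1, y = 1, z = 1,
                            loading_dorsal = 1, loading_ventral = 0),
    subject_jitter_vox = 0, rng_seed = 24)
  streams <- load_stream_table()
  parc <- synth_parcellation(cfg, streams)
  vals <- numeric(5)
  for (s in 1:5) {
    r <- generate_rest_run(cfg, s, parc = parc, streams = streams)
    nuis <- nuisance_set(r$motion, run = r$run,
                         compartments = r$compartments)
    sph <- build_sphere_roi(roi_spec("S", c(1, 1, 1), 4),
                            cfg$affine, cfg$grid_shape)
    ts <- first_eigenvariate(r$run, sph)
    bm <- seed_beta_map(r$run, ts, nuis)
    st <- stream_strength(bm, parc, streams)$streams
    vals[s] <- st$value[st$stream == "dorsal"]
  }
  expect_lt(abs(mean(vals) - cfg$parcel_loading) / cfg$parcel_loading, 0.1)
})

test_that("stream strength aggregates by voxel-weighted parcel means", {
  cfg <- small_cohort()
  streams <- load_stream_table()
  parc <- synth_parcellation(cfg, streams)
  # constant map: both streams equal the constant
  cmap <- volume_image(array(0.37, cfg$grid_shape), cfg$affine)
  st <- stream_strength(cmap, parc, streams)
  expect_equal(st$streams$value, c(0.37, 0.37))
  # indicator map on dorsal parcels
  dl <- parc$label_map[streams$area_name[streams$stream == "dorsal"]]
  ind <- array(as.numeric(parc$label_data %in% dl), cfg$grid_shape)
  st2 <- stream_strength(volume_image(ind, cfg$affine), parc, streams)
  expect_equal(st2$streams$value[st2$streams$stream == "dorsal"], 1)
  expect_equal(st2$streams$value[st2$streams$stream == "ventral"], 0)
  # random map equals a direct summation oracle
  set.seed(25)
  rnd <- array(rnorm(prod(cfg$grid_shape)), cfg$grid_shape)
  st3 <- stream_strength(volume_image(rnd, cfg$affine), parc, streams)
  oracle <- mean(rnd[parc$label_data %in% dl])
  expect_equal(st3$streams$value[st3$streams$stream == "dorsal"], oracle)
})

test_that("repeated-measures ANOVA matches its invariants", {
  # equal cell values per subject: zero interaction F
  d <- expand.grid(subject = 1:8, seed = c("A", "B", "C"),
                   stream = c("dorsal", "ventral"))
  d$value <- as.numeric(d$subject)   # subject main effect only
  an <- repeated_anova(d, within = c("seed", "stream"))
  # no cell deviates from its subject mean: zero interaction sum of squares
  expect_equal(an$ss[an$effect == "seed x stream"], 0, tolerance = 1e-12)
  expect_equal(an$df1[an$effect == "seed"], 2)
  expect_equal(an$df2[an$effect == "seed"], 14)
  # single-level factor and missing cells error
  expect_error(repeated_anova(d[d$stream == "dorsal", ],
                              within = c("seed", "stream")), "2 levels")
  expect_error(repeated_anova(d[-1, ], within = c("seed", "stream")),
               "unbalanced")
})

test_that("repeated-measures ANOVA agrees with a direct two-level oracle", {
  # with two seeds and two streams the interaction F equals a paired t^2
  # on the per-subject difference-of-differences
  set.seed(26)
  d <- expand.grid(subject = 1:12, seed = c("A", "B"),
                   stream = c("dorsal", "ventral"))
  d$value <- rnorm(nrow(d)) + ifelse(d$seed == "A" & d$stream == "dorsal",
                                     0.8, 0)
  an <- repeated_anova(d, within = c("seed", "stream"))
  dd <- sapply(1:12, function(s) {
    x <- d[d$subject == s, ]
    (x$value[x$seed == "A" & x$stream == "dorsal"] -
       x$value[x$seed == "A" & x$stream == "ventral"]) -
      (x$value[x$seed == "B" & x$stream == "dorsal"] -
         x$value[x$seed == "B" & x$stream == "ventral"])
  })
  tt <- t.test(dd)
  expect_equal(an$F[an$effect == "seed x stream"],
               unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(an$p[an$effect == "seed x stream"], tt$p.value,
               tolerance = 1e-8)
})

test_that("planted seed x stream interactions are detected with high power", {
  streams <- load_stream_table()
  hits <- 0
  for (c in 1:10) {
    cfg <- synthetic_cohort_config(n_subjects = 16,
                                   grid_shape = c(12, 12, 10),
                                   n_volumes = 80, rng_seed = 260 + c)
    parc <- synth_parcellation(cfg, streams)
    tab <- do.call(rbind, lapply(seq_len(cfg$n_subjects), function(s)
      subject_stream_strengths(cfg, s, parc, streams)))
    an <- repeated_anova(tab, within = c("seed", "stream"))
    if (an$p[an$effect == "seed x stream"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("motion screening applies the exclusion threshold", {
  m <- matrix(0, 50, 6)
  expect_true(screen_motion(m)$pass)
  m[30, 2] <- 3.5
  expect_false(screen_motion(m)$pass)
  expect_true(screen_motion(m, threshold_mm = 4)$pass)
})

test_that("group maps find planted blobs and stay empty for null contrasts", {
  set.seed(27)
  g <- test_grid(shape = c(10, 10, 8))
  mk <- function(blob) {
    a <- array(rnorm(prod(g$shape), sd = 0.5), g$shape)
    if (blob) a[4:6, 4:6, 3:5] <- a[4:6, 4:6, 3:5] + 3
    volume_image(a, g$affine)
  }
  res <- group_map(lapply(1:8, function(i) mk(TRUE)), n_perm = 200)
  sig <- res$clusters[res$clusters$p_fwe < 0.05, ]
  # the planted 3x3x3 blob emerges as the dominant significant cluster
  expect_true(27 %in% sig$n_voxels)
  expect_equal(max(res$clusters$mass),
               res$clusters$mass[res$clusters$n_voxels == 27])
  # paired contrast of a map with itself: all-zero differences, no clusters
  zero <- lapply(1:8, function(i) volume_image(array(0, g$shape), g$affine))
  res0 <- group_map(zero, n_perm = 50)
  expect_equal(nrow(res0$clusters), 0)
  expect_error(group_map(zero[1]), "at least 2")
})

test_that("sign-flip cluster FWE is calibrated near the nominal level", {
  set.seed(28)
  g <- test_grid(shape = c(10, 10, 8))
  n_sim <- 120
  any_sig <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    maps <- lapply(1:8, function(s)
      volume_image(array(rnorm(prod(g$shape)), g$shape), g$affine))
    res <- group_map(maps, n_perm = 99, rng_seed = i)
    any_sig[i] <- any(res$clusters$p_fwe <= 0.05)
  }
  rate <- mean(any_sig)
  # exact binomial 99% band around 0.05 at 120 simulations
  expect_gte(rate, qbinom(0.005, n_sim, 0.05) / n_sim)
  expect_lte(rate, qbinom(0.995, n_sim, 0.05) / n_sim)
})

test_that("26-connectivity joins corner-touching voxels into one cluster", {
  a <- array(FALSE, c(4, 4, 4))
  a[1, 1, 1] <- TRUE
  a[2, 2, 2] <- TRUE   # corner neighbour
  lab <- streamconn:::label_components_26(a)
  expect_equal(max(lab), 1)
  a[4, 4, 4] <- TRUE   # isolated
  lab2 <- streamconn:::label_components_26(a)
  expect_equal(max(lab2), 2)
})
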