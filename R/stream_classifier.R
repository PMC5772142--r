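#' Build a dorsal/ventral training set from parcel connectivity patterns
#'
#' For every parcel in the stream table, computes the whole-brain
#' connectivity beta map with the parcel's first eigenvariate as seed
#' (same procedure as the seed-region maps) and flattens it over a shared
#' in-brain voxel set.
#'
#' @param run A 4D [volume_image()] resting-state run.
#' @param parc A [parcellation_volume()] on the run's grid.
#' @param streams A `stream_table` (needs both classes present).
#' @param nuisance An [nuisance_set()] (or `NULL`).
#' @param brain_mask Optional `roi_mask` defining the shared voxel set;
#'   defaults to all voxels.
#' @param highpass_s High-pass cutoff (s).
#' @return A `training_set`: list with `patterns` (item x voxel matrix),
#'   `labels` (dorsal/ventral), `area_names`, `voxel_index`.
#' @export
build_training_set <- function(run, parc, streams, nuisance = NULL,
                               brain_mask = NULL, highpass_s = 128) {
  if (length(unique(streams$stream)) < 2L) {
    stop("training requires both dorsal and ventral classes")
  }
  d <- dim(run$data)
  vox_idx <- if (is.null(brain_mask)) seq_len(prod(d[1:3])) else
    mask_linear_index(brain_mask)
  pats <- matrix(NA_real_, nrow = nrow(streams), ncol = length(vox_idx))
  for (i in seq_len(nrow(streams))) {
    m <- parcel_mask(parc, streams$area_name[i])
    ts <- first_eigenvariate(run, m)
    bm <- seed_beta_map(run, ts, nuisance, highpass_s = highpass_s,
                        seed_name = streams$area_name[i])
    pats[i, ] <- bm$data[vox_idx]
  }
  structure(list(patterns = pats, labels = streams$stream,
                 area_names = streams$area_name, voxel_index = vox_idx),
            class = "training_set")
}

#' Flatten a beta map onto a training set's voxel index
#' @param beta A `beta_map`.
#' @param train A `training_set`.
#' @export
flatten_query <- function(beta, train) {
  as.numeric(beta$data)[train$voxel_index]
}

#' k-nearest-neighbour classification under city-block distance
#'
#' Assigns the majority label of the `k` training items nearest to the
#' query in city-block distance. At even `k` a tied vote is broken by the
#' label of the single nearest item (deterministic).
#'
#' @param query Numeric vector (flattened beta map).
#' @param train A `training_set` (or list with `patterns`, `labels`).
#' @param k Number of neighbours (1 <= k <= number of items).
#' @return Character label (`"dorsal"` or `"ventral"`).
#' @export
knn_classify <- function(query, train, k) {
  P <- train$patterns
  labs <- train$labels
  n <- nrow(P)
  if (k < 1L || k > n) stop("k must be between 1 and ", n)
  if (k == n) {
    warning("k equals the training-set size; the majority class wins ",
            "regardless of the query")
  }
  dists <- rowSums(abs(sweep(P, 2, query)))
  ord <- order(dists)
  top <- labs[ord[seq_len(k)]]
  votes <- table(top)
  winners <- names(votes)[votes == max(votes)]
  if (length(winners) == 1L) winners else labs[ord[1]]
}

#' Sweep k over a range and aggregate classification outcomes
#'
#' Classifies every query at every `k` and summarizes the probability of a
#' dorsal outcome per seed, aggregated over subjects and `k` values as
#' well as per `k`.
#'
#' @param queries Data frame-like list of queries: a data.frame with
#'   columns `subject`, `seed` and a list-column `pattern`, or a list of
#'   lists with those fields.
#' @param train A `training_set`.
#' @param k_range Integer vector of `k` values (default 2:8, one less than
#'   the ventral-class size of the packaged stream table).
#' @return List with `outcomes` (data.frame `subject`, `seed`, `k`,
#'   `label`), `dorsal_probability` (per seed), and `per_k` (per seed and
#'   k).
#' @export
k_sweep <- function(queries, train, k_range = 2:8) {
  if (any(k_range < 1L)) stop("k_range must contain only positive k")
  if (any(k_range > nrow(train$patterns))) {
    stop("k_range exceeds the training-set size")
  }
  if (is.data.frame(queries)) {
    queries <- lapply(seq_len(nrow(queries)), function(i) {
      list(subject = queries$subject[i], seed = queries$seed[i],
           pattern = queries$pattern[[i]])
    })
  }
  if (!length(queries)) stop("empty query set")
  rows <- list()
  for (q in queries) {
    dists <- rowSums(abs(sweep(train$patterns, 2, q$pattern)))
    ord <- order(dists)
    for (k in k_range) {
      top <- train$labels[ord[seq_len(k)]]
      votes <- table(top)
      winners <- names(votes)[votes == max(votes)]
      lab <- if (length(winners) == 1L) winners else train$labels[ord[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = q$subject, seed = q$seed, k = k, label = lab)
    }
  }
  outcomes <- do.call(rbind, rows)
  agg <- stats::aggregate(label ~ seed, data = outcomes,
                          FUN = function(x) mean(x == "dorsal"))
  names(agg)[2] <- "dorsal_probability"
  per_k <- stats::aggregate(label ~ seed + k, data = outcomes,
                            FUN = function(x) mean(x == "dorsal"))
  names(per_k)[3] <- "dorsal_probability"
  list(outcomes = outcomes, dorsal_probability = agg, per_k = per_k)
}

#' Friedman comparison of classification outcomes across seeds
#'
#' Binary outcomes (dorsal = 1, ventral = 0) are compared across seed
#' regions with Friedman's rank test, blocking on subject x k cells
#' (midrank ties). Pairwise seed follow-ups use the same test on each seed
#' pair.
#'
#' @param outcomes data.frame from [k_sweep()] (`subject`, `seed`, `k`,
#'   `label`).
#' @return List with `overall` (statistic, df, p) and `pairwise`
#'   (data.frame per seed pair).
#' @export
compare_outcomes <- function(outcomes) {
  outcomes$y <- as.numeric(outcomes$label == "dorsal")
  outcomes$block <- interaction(outcomes$subject, outcomes$k, drop = TRUE)
  wide <- stats::xtabs(y ~ block + seed, data = outcomes)
  counts <- stats::xtabs(~ block + seed, data = outcomes)
  if (any(counts != 1L)) {
    stop("unbalanced layout: every subject x k cell needs each seed once")
  }
  # fully tied blocks make the rank statistic 0/0; report no effect
  safe_friedman <- function(m) {
    f <- stats::friedman.test(m)
    if (!is.finite(f$statistic)) {
      f$statistic <- 0
      f$p.value <- 1
    }
    f
  }
  ft <- safe_friedman(as.matrix(wide))
  seeds <- colnames(wide)
  pw <- NULL
  if (length(seeds) > 2L) {
    pairs <- utils::combn(seeds, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      f <- safe_friedman(as.matrix(wide[, pairs[, i]]))
      data.frame(seed_a = pairs[1, i], seed_b = pairs[2, i],
                 statistic = unname(f$statistic),
                 df = unname(f$parameter), p = f$p.value)
    }))
  }
  list(overall = data.frame(statistic = unname(ft$statistic),
                            df = unname(ft$parameter), p = ft$p.value),
       pairwise = pw)
}
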