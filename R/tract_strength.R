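#' Select white-matter boundary voxels nearest a seed coordinate
#'
#' Returns the `n` voxels of the grey/white boundary mask whose world-space
#' centres are closest to the seed coordinate. Ties at the distance cutoff
#' are broken by lexicographic voxel order (deterministic).
#'
#' @param wm_boundary An [roi_mask()] of boundary voxels.
#' @param seed_coord_mm Length-3 world coordinate (mm).
#' @param n Number of seed voxels (default 20).
#' @return An `roi_mask` of the selected voxels.
#' @export
select_boundary_seeds <- function(wm_boundary, seed_coord_mm, n = 20) {
  idx <- wm_boundary$voxel_indices
  if (nrow(idx) < n) {
    stop("boundary mask has ", nrow(idx), " voxels; ", n, " required")
  }
  world <- voxel_to_world(idx, wm_boundary$affine)
  d2 <- (world[, 1] - seed_coord_mm[1])^2 +
    (world[, 2] - seed_coord_mm[2])^2 +
    (world[, 3] - seed_coord_mm[3])^2
  ord <- order(d2, idx[, 1], idx[, 2], idx[, 3])
  sel <- idx[ord[seq_len(n)], , drop = FALSE]
  roi_mask_from_indices(sel, wm_boundary$affine, wm_boundary$shape,
                        name = "boundary_seeds")
}

#' Log-normalized tractography connection strength
#'
#' Converts streamline path counts into the anatomical connection-strength
#' statistic: `log10((count + 1) / total)`, i.e. the count normalized by
#' the seed's total valid streamlines with a +1 pseudo-count so zero-count
#' cells stay finite, averaged over all records contributing to one
#' (subject, seed, hemisphere, stream) cell.
#'
#' @param records data.frame with columns `subject`, `seed`, `hemisphere`,
#'   `stream`, `count`, `total`.
#' @param log_base Logarithm base (default 10).
#' @param pseudo Pseudo-count added to `count` (default 1).
#' @return data.frame with one row per cell: `subject`, `seed`,
#'   `hemisphere`, `stream`, `value`.
#' @export
tract_strength <- function(records, log_base = 10, pseudo = 1) {
  req <- c("subject", "seed", "hemisphere", "stream", "count", "total")
  if (!all(req %in% names(records))) {
    stop("records need columns: ", paste(req, collapse = ", "))
  }
  if (any(records$total <= 0)) stop("total streamlines must be > 0")
  if (any(records$count < 0 | records$count > records$total)) {
    stop("counts must lie in [0, total]")
  }
  records$value <- log((records$count + pseudo) / records$total,
                       base = log_base)
  out <- stats::aggregate(value ~ subject + seed + hemisphere + stream,
                          data = records, FUN = mean)
  out[order(out$subject, out$seed, out$hemisphere, out$stream), ,
      drop = FALSE]
}

#' Repeated-measures ANOVA on tract strengths
#'
#' Seed x stream (optionally x hemisphere) within-subject ANOVA on the
#' log-normalized strengths, with Bonferroni-corrected pairwise 2 x 2
#' follow-ups over seed pairs.
#'
#' @param strengths Output of [tract_strength()] (or any long table with
#'   `subject`, `seed`, `stream`, optional `hemisphere`, `value`).
#' @param with_hemisphere Include hemisphere as a third factor.
#' @return List with `anova` (an `anova_result`) and `followups`
#'   (pairwise seed x stream interactions, Bonferroni-corrected).
#' @export
tract_anova <- function(strengths, with_hemisphere = FALSE) {
  if (length(unique(strengths$seed)) < 2L ||
      length(unique(strengths$stream)) < 2L) {
    stop("a seed x stream ANOVA needs at least 2 seeds and 2 streams")
  }
  within <- c("seed", "stream")
  data <- strengths
  if (with_hemisphere) {
    within <- c(within, "hemisphere")
  } else if ("hemisphere" %in% names(strengths) &&
             length(unique(strengths$hemisphere)) > 1L) {
    # collapse hemispheres by averaging
    data <- stats::aggregate(value ~ subject + seed + stream,
                             data = strengths, FUN = mean)
  }
  res <- repeated_anova(data, within = within)
  fu <- tryCatch(
    pairwise_interactions(if (with_hemisphere)
      stats::aggregate(value ~ subject + seed + stream, data = data, FUN = mean)
      else data, "seed", "stream"),
    error = function(e) NULL)
  list(anova = res, followups = fu)
}
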