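#' Extract a connectivity fingerprint from a beta map
#'
#' Computes the mean beta inside each target sphere. By convention negative
#' arm values are replaced by zero (`mask_at_zero`), retaining only
#' positive coupling, applied per subject before any group summarizing.
#'
#' @param beta A 3D `beta_map` / [volume_image()].
#' @param targets List of [roi_spec()]s (fixed arm order).
#' @param mask_at_zero Replace negative means by 0 (default `TRUE`).
#' @return A `fingerprint`: named numeric vector (one value per target, in
#'   table order) with attributes `masked`, `seed`, `subject`.
#' @export
extract_fingerprint <- function(beta, targets, mask_at_zero = TRUE) {
  stopifnot(inherits(beta, "volume_image"), length(targets) >= 1L)
  d <- dim(beta$data)[1:3]
  vals <- vapply(targets, function(tg) {
    m <- tryCatch(build_sphere_roi(tg, beta$affine, d),
                  error = function(e) stop("target '", tg$name, "': ",
                                           conditionMessage(e)))
    mean(beta$data[mask_linear_index(m)])
  }, numeric(1))
  names(vals) <- vapply(targets, `[[`, character(1), "name")
  if (mask_at_zero) vals <- pmax(vals, 0)
  structure(vals, masked = mask_at_zero,
            seed = attr(beta, "seed"), subject = attr(beta, "subject"),
            class = c("fingerprint", "numeric"))
}

#' Jointly normalize a pair of fingerprints to [0, 1]
#'
#' A single affine map sends the minimum over the combined arms of both
#' fingerprints to 0 and the maximum to 1, applied identically to both, so
#' the pair stays comparable after rescaling.
#'
#' @param a,b Fingerprints (numeric vectors, same arm order).
#' @return List of the two normalized vectors.
#' @export
normalize_pair <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprints differ in arm count")
  lo <- min(a, b)
  hi <- max(a, b)
  if (hi - lo < .Machine$double.eps) {
    stop("degenerate normalization range: all arms equal across the pair")
  }
  list(a = (a - lo) / (hi - lo), b = (b - lo) / (hi - lo))
}

#' City-block (Manhattan) distance between fingerprints
#'
#' Sum of absolute differences over all fingerprint arms.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar distance.
#' @export
cityblock <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  sum(abs(a - b))
}

#' Permutation test for the difference between two fingerprints
#'
#' The observed statistic is the city-block distance between the
#' jointly-normalized group-mean fingerprints of conditions A and B over
#' paired subjects. The null is built by independently swapping each
#' subject's A/B labels, recomputing group means, re-normalizing the
#' permuted pair (normalization inside the loop, so the test is not biased
#' by the observed range), and recomputing the distance. The p value uses
#' the add-one convention `p = (1 + #permuted >= observed) / (1 + n_perm)`
#' and can therefore never be zero.
#'
#' @param arms_a,arms_b Subject x arm matrices of per-subject fingerprints
#'   for the two regions (same subjects, same arm order).
#' @param n_perm Number of label permutations (default 5000).
#' @param rng_seed Integer seed for the permutation stream.
#' @return A `fingerprint_test`: list with `observed_d`, `null`
#'   (permuted distances), `p`, `n_perm`, `n_subjects`.
#' @export
fingerprint_permutation_test <- function(arms_a, arms_b, n_perm = 5000,
                                         rng_seed = 1L) {
  A <- as.matrix(arms_a)
  B <- as.matrix(arms_b)
  if (!identical(dim(A), dim(B))) stop("fingerprint matrices must match")
  n <- nrow(A)
  if (n < 2L) stop("at least 2 subjects are required")
  stat <- function(mA, mB) {
    nm <- normalize_pair(mA, mB)
    cityblock(nm$a, nm$b)
  }
  observed <- stat(colMeans(A), colMeans(B))
  set.seed(as.integer(rng_seed))
  S <- matrix(stats::runif(n_perm * n) < 0.5, nrow = n_perm)  # TRUE = swap
  # group means under each relabelling, vectorized over permutations
  mA_perm <- (S %*% B + (!S) %*% A) / n
  mB_perm <- (S %*% A + (!S) %*% B) / n
  lo <- pmin(apply(mA_perm, 1, min), apply(mB_perm, 1, min))
  hi <- pmax(apply(mA_perm, 1, max), apply(mB_perm, 1, max))
  rng <- hi - lo
  null <- rowSums(abs(mA_perm - mB_perm)) / ifelse(rng > 0, rng, NA_real_)
  null[!is.finite(null)] <- 0
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  structure(list(observed_d = observed, null = null, p = p,
                 n_perm = n_perm, n_subjects = n),
            class = "fingerprint_test")
}

#' @export
print.fingerprint_test <- function(x, ...) {
  cat(sprintf("<fingerprint_test> d = %.4f, p = %.4g (%d permutations, %d subjects)\n",
              x$observed_d, x$p, x$n_perm, x$n_subjects))
  invisible(x)
}

#' Per-arm logistic attribution of a fingerprint difference
#'
#' For each arm, regresses the region label (A = 0, B = 1) on that arm's
#' value across the stacked per-subject observations via logistic
#' regression, reporting the Wald p value, uncorrected for multiple
#' comparisons. Arms that perfectly separate the labels are flagged rather
#' than treated as fatal.
#'
#' @param arms_a,arms_b Subject x arm matrices (same arm order).
#' @return data.frame with columns `target`, `direction` (+1 when larger
#'   values favour region B), `p`, `separation` (logical flag).
#' @export
arm_attribution <- function(arms_a, arms_b) {
  A <- as.matrix(arms_a)
  B <- as.matrix(arms_b)
  if (!identical(dim(A), dim(B))) stop("fingerprint matrices must match")
  labels <- rep(c(0, 1), times = c(nrow(A), nrow(B)))
  arm_names <- colnames(A) %||% paste0("arm", seq_len(ncol(A)))
  out <- lapply(seq_len(ncol(A)), function(j) {
    x <- c(A[, j], B[, j])
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(labels ~ x, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    # converged-at-boundary separation leaves no warning but fits the
    # labels exactly
    if (all(abs(stats::fitted(fit) - labels) < 1e-6)) sep <- TRUE
    cf <- summary(fit)$coefficients
    if (nrow(cf) < 2L || stats::sd(x) == 0) {
      return(data.frame(target = arm_names[j], direction = 0,
                        p = 1, separation = FALSE))
    }
    data.frame(target = arm_names[j],
               direction = sign(cf["x", "Estimate"]),
               p = cf["x", "Pr(>|z|)"],
               separation = sep)
  })
  do.call(rbind, out)
}

#' Export fingerprints as a long table (spider-plot data)
#'
#' @param fingerprints Named list of fingerprints (or subject x arm
#'   matrices with a `seed` name each).
#' @return Long data.frame `seed`, `target`, `value`.
#' @export
fingerprint_table <- function(fingerprints) {
  out <- lapply(names(fingerprints), function(nm) {
    fp <- fingerprints[[nm]]
    if (is.matrix(fp)) fp <- colMeans(fp)
    data.frame(seed = nm, target = names(fp) %||% seq_along(fp),
               value = as.numeric(fp))
  })
  do.call(rbind, out)
}
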