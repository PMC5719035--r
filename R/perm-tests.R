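# Permutation tests on aligned shapes: pairwise disparity differences
# (residual-randomization null by default) and pairwise mean-shape
# differences, plus a simulation-based power analysis for detecting
# variance increases.

# Canonicalise specimen order (lexicographic by coordinates) so seeded
# permutations give the same P whatever order specimens arrive in.
.canonicalise <- function(x, groups) {
  ord <- canonical_row_order(x)
  list(x = x[ord, , drop = FALSE], groups = groups[ord])
}

#' Pairwise permutation test for differences in Procrustes variance
#'
#' For each pair of groups, the observed statistic is the absolute
#' difference of the two groups' Procrustes variances (divisor n). With
#' `method = "raw"` (default) the null permutes raw specimens between
#' the pair and recomputes each pseudo-group's variance about its own
#' mean; under the hypothesis that the two groups share one
#' distribution this is exchangeable and exactly calibrated.
#' `method = "residual"` instead permutes the per-specimen squared
#' residual distances from their own group means (a group's Procrustes
#' variance is the mean of those scalars); it retains power when the
#' groups differ strongly in mean shape but is slightly
#' anti-conservative, because own-mean centering breaks exchangeability.
#' P values use the add-one convention
#' `(1 + #(null >= obs)) / (n_perm + 1)` and are never exactly zero.
#'
#' @param shapes n x p matrix (or `aligned_shape_set`).
#' @param groups Group labels of length n; singleton groups are dropped
#'   with a warning.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed; fixed seed gives identical P values,
#'   independent of specimen order.
#' @param method `"raw"` (exchangeable specimen permutation, default) or
#'   `"residual"` (scalar residual randomization).
#' @return A symmetric matrix of P values with group names on both
#'   dimensions (diagonal NA).
#' @export
disparity_permutation_test <- function(shapes, groups, n_perm = 999,
                                       seed = NULL,
                                       method = c("raw", "residual")) {
  method <- match.arg(method)
  if (n_perm < 99) stopf("`n_perm` must be at least 99")
  x <- as_shape_matrix(shapes)
  groups <- as.character(groups)
  keep_lv <- names(which(table(groups) >= 2))
  if (length(keep_lv) < 2) stopf("need at least 2 groups with n >= 2")
  if (length(keep_lv) < length(unique(groups)))
    warning("dropping singleton group(s) from disparity test")
  keep <- groups %in% keep_lv
  cc <- .canonicalise(x[keep, , drop = FALSE], groups[keep])
  x <- cc$x; groups <- cc$groups
  lv <- sort(unique(groups))

  # squared residual distances from own group mean; a group's Procrustes
  # variance (divisor n) is the mean of these scalars
  sqdist <- numeric(nrow(x))
  for (l in lv) {
    idx <- groups == l
    dev <- sweep(x[idx, , drop = FALSE], 2, colMeans(x[idx, , drop = FALSE]))
    sqdist[idx] <- rowSums(dev^2)
  }

  p_mat <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  with_seed(seed, {
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (j <= i) next
      ia <- which(groups == lv[i]); ib <- which(groups == lv[j])
      na <- length(ia)
      obs <- abs(mean(sqdist[ia]) - mean(sqdist[ib]))
      if (method == "residual") {
        pool <- sqdist[c(ia, ib)]
        n_pool <- length(pool)
        null <- vapply(seq_len(n_perm), function(b) {
          pa <- sample.int(n_pool, na)
          abs(mean(pool[pa]) - mean(pool[-pa]))
        }, 1.0)
      } else {
        pool <- x[c(ia, ib), , drop = FALSE]
        n_pool <- nrow(pool)
        null <- vapply(seq_len(n_perm), function(b) {
          pa <- sample.int(n_pool, na)
          sel <- rep(FALSE, n_pool); sel[pa] <- TRUE
          abs(.pv_of_rows(pool, sel) - .pv_of_rows(pool, !sel))
        }, 1.0)
      }
      p <- (1 + sum(null >= obs - 1e-15)) / (n_perm + 1)
      p_mat[i, j] <- p_mat[j, i] <- p
    }
  })
  p_mat
}

#' Pairwise permutation test for mean-shape differences
#'
#' Observed statistic: Euclidean distance between the two group mean
#' shapes in the aligned coordinate space (the Procrustes distance for
#' shapes already superimposed). Null: raw group labels permuted within
#' the pair. `method = "exact"` enumerates all label assignments (only
#' feasible for small pairs) and reports the exact permutation P.
#'
#' @inheritParams disparity_permutation_test
#' @param method `"sample"` (Monte Carlo, add-one P) or `"exact"`.
#' @return Symmetric matrix of P values (diagonal NA).
#' @export
mean_shape_permutation_test <- function(shapes, groups, n_perm = 999,
                                        seed = NULL,
                                        method = c("sample", "exact")) {
  method <- match.arg(method)
  if (method == "sample" && n_perm < 99) stopf("`n_perm` must be at least 99")
  x <- as_shape_matrix(shapes)
  groups <- as.character(groups)
  cc <- .canonicalise(x, groups)
  x <- cc$x; groups <- cc$groups
  lv <- sort(unique(groups))
  if (length(lv) < 2) stopf("need at least 2 groups")

  mean_dist <- function(m, sel) {
    sqrt(sum((colMeans(m[sel, , drop = FALSE]) -
                colMeans(m[!sel, , drop = FALSE]))^2))
  }
  p_mat <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  with_seed(seed, {
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (j <= i) next
      ia <- which(groups == lv[i]); ib <- which(groups == lv[j])
      pool <- x[c(ia, ib), , drop = FALSE]
      na <- length(ia); n_pool <- nrow(pool)
      sel0 <- rep(FALSE, n_pool); sel0[seq_len(na)] <- TRUE
      obs <- mean_dist(pool, sel0)
      if (method == "exact") {
        combs <- utils::combn(n_pool, na)
        null <- apply(combs, 2, function(ix) {
          sel <- rep(FALSE, n_pool); sel[ix] <- TRUE
          mean_dist(pool, sel)
        })
        p <- sum(null >= obs - 1e-15) / length(null)
      } else {
        null <- vapply(seq_len(n_perm), function(b) {
          sel <- rep(FALSE, n_pool)
          sel[sample.int(n_pool, na)] <- TRUE
          mean_dist(pool, sel)
        }, 1.0)
        p <- (1 + sum(null >= obs - 1e-15)) / (n_perm + 1)
      }
      p_mat[i, j] <- p_mat[j, i] <- p
    }
  })
  p_mat
}

#' Power to detect a variance increase between two groups
#'
#' Simulates two groups of isotropic Gaussian shapes whose per-coordinate
#' variances differ by `variance_ratio`, applies
#' [disparity_permutation_test()], and reports the fraction of replicates
#' rejecting at `alpha`, with a binomial standard error. Mirrors the
#' sample-size analysis used to justify group sizes in variance
#' comparisons.
#'
#' @param n_per_group Specimens per group.
#' @param variance_ratio Ratio of group-2 to group-1 per-coordinate
#'   variance (1 = null).
#' @param p Number of shape coordinates simulated (default 18, i.e. six
#'   3D landmarks' worth of variation).
#' @param base_sd Per-coordinate SD of group 1.
#' @param alpha Nominal test level.
#' @param reps Number of simulated datasets (>= 100).
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @return A list with `power`, `se`, `reps`, `alpha`, `rejections`.
#' @export
variance_power_simulation <- function(n_per_group, variance_ratio,
                                      p = 18, base_sd = 0.01,
                                      alpha = 0.05, reps = 200,
                                      n_perm = 199, seed = NULL) {
  if (reps < 100) stopf("`reps` must be at least 100")
  if (variance_ratio <= 0) stopf("`variance_ratio` must be positive")
  rej <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      g1 <- matrix(stats::rnorm(n_per_group * p, 0, base_sd), n_per_group)
      g2 <- matrix(stats::rnorm(n_per_group * p, 0,
                                base_sd * sqrt(variance_ratio)), n_per_group)
      pm <- disparity_permutation_test(rbind(g1, g2),
                                       rep(c("a", "b"), each = n_per_group),
                                       n_perm = n_perm,
                                       seed = sample.int(2^30, 1))
      pm["a", "b"] <= alpha
    }, TRUE)
  })
  k <- sum(rej)
  power <- k / reps
  list(power = power, se = sqrt(power * (1 - power) / reps),
       reps = reps, alpha = alpha, rejections = k)
}
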