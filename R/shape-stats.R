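# Shape-space statistics on Procrustes-aligned coordinates: ordination,
# covariate standardization, batch-offset removal, multivariate
# regression / regression scores, and morphological disparity.

as_shape_matrix <- function(shapes) {
  if (inherits(shapes, "aligned_shape_set")) shapes$shapes else as.matrix(shapes)
}

#' Principal component analysis of shapes
#'
#' Eigendecomposition of the covariance of centered rows. Component signs
#' follow a fixed convention (the largest-magnitude loading of each
#' component is positive) so results are reproducible across platforms.
#'
#' @param shapes n x p matrix (or an `aligned_shape_set`).
#' @return A list with `scores` (n x m), `loadings` (p x m),
#'   `eigenvalues` (variances), and `proportion` (fractions of total
#'   variance; sums to 1).
#' @export
shape_pca <- function(shapes) {
  x <- as_shape_matrix(shapes)
  if (nrow(x) < 2) stopf("need at least 2 shapes")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    v[which.max(abs(v))] < 0
  }, TRUE)
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  ev <- pc$sdev^2
  list(scores = pc$x, loadings = pc$rotation, eigenvalues = ev,
       proportion = ev / sum(ev))
}

#' Remove a covariate's effect from aligned shapes
#'
#' Per-coordinate linear regression on a covariate; the returned set
#' carries the residuals plus the grand mean shape, so the residual
#' shapes are uncorrelated with the covariate. Embryo data are
#' standardized on a stage covariate (tail-somite count) and neonate
#' data on centroid size.
#'
#' @param aligned An `aligned_shape_set`.
#' @param covariate Name of a metadata column (`"stage"`,
#'   `"size_covariate"`, or `"centroid_size"`), or a numeric vector.
#' @return The input set with `shapes` replaced by standardized shapes.
#' @export
standardize_shapes <- function(aligned, covariate = "stage") {
  stopifnot(inherits(aligned, "aligned_shape_set"))
  x <- if (is.character(covariate)) {
    if (!covariate %in% names(aligned$metadata))
      stopf("covariate `%s` not found in metadata", covariate)
    aligned$metadata[[covariate]]
  } else as.numeric(covariate)
  if (any(!is.finite(x))) stopf("covariate has missing values")
  if (stats::sd(x) == 0) stopf("covariate is constant")
  xc <- x - mean(x)
  grand <- colMeans(aligned$shapes)
  centered <- sweep(aligned$shapes, 2, grand)
  beta <- crossprod(xc, centered) / sum(xc^2)     # 1 x p slopes
  resid <- centered - outer(xc, as.vector(beta))
  aligned$shapes <- sweep(resid, 2, grand, `+`)
  aligned
}

#' Remove lab-of-origin offsets using wild-type group means
#'
#' For each non-reference lab, subtracts the difference between that
#' lab's wild-type mean shape and the reference lab's wild-type mean from
#' every specimen of the lab, so that the wild-type groups coincide
#' afterwards.
#'
#' @param aligned An `aligned_shape_set`.
#' @param wild_type Genotype label of the wild-type group.
#' @param reference_lab Optional reference lab; defaults to the first lab
#'   (alphabetically) containing wild-type specimens.
#' @return The input set with lab offsets removed.
#' @export
remove_lab_offset <- function(aligned, wild_type, reference_lab = NULL) {
  stopifnot(inherits(aligned, "aligned_shape_set"))
  md <- aligned$metadata
  labs <- sort(unique(md$lab))
  wt <- md$genotype == wild_type
  for (l in labs) {
    if (!any(wt & md$lab == l))
      stopf("lab `%s` has no wild-type specimens", l)
  }
  if (is.null(reference_lab)) reference_lab <- labs[1]
  if (!reference_lab %in% labs) stopf("unknown reference lab `%s`", reference_lab)
  ref_mean <- colMeans(aligned$shapes[wt & md$lab == reference_lab, , drop = FALSE])
  for (l in setdiff(labs, reference_lab)) {
    offset <- colMeans(aligned$shapes[wt & md$lab == l, , drop = FALSE]) - ref_mean
    rows <- md$lab == l
    aligned$shapes[rows, ] <- sweep(aligned$shapes[rows, , drop = FALSE], 2, offset)
  }
  aligned
}

#' Multivariate regression of shape on a covariate
#'
#' Ordinary least squares of every coordinate on a single covariate.
#' `r_squared` is the fraction of the total (centered) Procrustes sum of
#' squares explained; `regression_scores` are the projections of the
#' centered shapes onto the unit-normalized coefficient vector -- the
#' one-dimensional shape score (identical to the common allometric
#' component when computed from a pooled analysis).
#'
#' @param shapes n x p matrix (or `aligned_shape_set`).
#' @param covariate Numeric vector of length n, non-constant.
#' @return An object of class `shape_regression`: `coefficients` (p),
#'   `intercept` (p), `r_squared`, `regression_scores` (n),
#'   `residual_shapes` (n x p, residuals plus grand mean), `fitted`.
#' @export
shape_regression <- function(shapes, covariate) {
  y <- as_shape_matrix(shapes)
  x <- as.numeric(covariate)
  if (length(x) != nrow(y)) stopf("covariate length must match shape count")
  if (nrow(y) < 3) stopf("need at least 3 specimens")
  if (stats::sd(x) == 0) stopf("covariate is constant")
  xc <- x - mean(x)
  grand <- colMeans(y)
  yc <- sweep(y, 2, grand)
  beta <- as.vector(crossprod(xc, yc) / sum(xc^2))  # p slopes
  fitted_c <- outer(xc, beta)
  resid <- yc - fitted_c
  ss_tot <- sum(yc^2)
  r2 <- if (ss_tot > 0) sum(fitted_c^2) / ss_tot else NA_real_
  unit <- beta / sqrt(sum(beta^2))
  structure(list(
    coefficients = beta,
    intercept = grand - mean(x) * beta,
    r_squared = r2,
    regression_scores = as.vector(yc %*% unit),
    residual_shapes = sweep(resid, 2, grand, `+`),
    fitted = sweep(fitted_c, 2, grand, `+`)
  ), class = "shape_regression")
}

#' Procrustes variance (morphological disparity) per group
#'
#' For each group, the mean squared deviation of its shapes from the
#' group mean shape, summed over all coordinates. The divisor is `n`
#' (population form, the convention of the morphological-disparity
#' literature) by default; set `divisor = "n-1"` for the sample form.
#'
#' @param shapes n x p matrix (or `aligned_shape_set`).
#' @param groups Group labels of length n.
#' @param divisor `"n"` (default) or `"n-1"`.
#' @return A data.frame with `group`, `n`, `disparity` (NA for singleton
#'   groups, which are flagged in `defined`).
#' @export
procrustes_variance <- function(shapes, groups, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  x <- as_shape_matrix(shapes)
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) stopf("`groups` length must match shape count")
  lv <- unique(groups)
  out <- data.frame(group = lv, n = NA_integer_, disparity = NA_real_,
                    defined = TRUE, stringsAsFactors = FALSE)
  for (i in seq_along(lv)) {
    g <- x[groups == lv[i], , drop = FALSE]
    n <- nrow(g)
    out$n[i] <- n
    denom <- if (divisor == "n") n else n - 1
    if (denom < 1 || n < 2) {
      out$defined[i] <- FALSE
      next
    }
    dev <- sweep(g, 2, colMeans(g))
    out$disparity[i] <- sum(dev^2) / denom
  }
  out
}

# Internal: fast per-group Procrustes variance of a residual matrix given
# a 0/1 group indicator; divisor n.
.pv_of_rows <- function(m, idx) {
  g <- m[idx, , drop = FALSE]
  sum(g^2) / nrow(g) - sum(colMeans(g)^2)
}
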