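#' A single specimen's landmark configuration
#'
#' @param coords K x 3 numeric matrix of raw landmark coordinates
#'   (arbitrary units); all finite, K >= 3.
#' @param specimen_id Specimen label.
#' @param genotype Genotype label.
#' @param lab Lab-of-origin (batch) label.
#' @param stage Developmental stage covariate (e.g. tail-somite count),
#'   or `NA`.
#' @param size_covariate Size covariate used for neonates, or `NA`.
#' @return An object of class `landmark_configuration`.
#' @export
landmark_configuration <- function(coords, specimen_id, genotype = NA,
                                   lab = NA, stage = NA,
                                   size_covariate = NA) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stopf("`coords` must be a K x 3 matrix")
  if (nrow(coords) < 3) stopf("need at least 3 landmarks")
  if (!all(is.finite(coords)))
    stopf("specimen %s has non-finite landmark coordinates", specimen_id)
  structure(list(coords = unname(coords), specimen_id = as.character(specimen_id),
                 genotype = genotype, lab = lab, stage = stage,
                 size_covariate = size_covariate),
            class = "landmark_configuration")
}

centroid_size <- function(coords) {
  centered <- sweep(coords, 2, colMeans(coords))
  sqrt(sum(centered^2))
}

# Optimal proper rotation R (no reflection) minimizing ||X %*% R - target||.
solve_rotation <- function(x, target) {
  m <- crossprod(x, target)
  sv <- svd(m)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

flatten_shape <- function(coords) as.vector(t(coords))
unflatten_shape <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Generalized Procrustes analysis of 3D landmark configurations
#'
#' Translates each configuration to centroid origin, scales to unit
#' centroid size, then iteratively rotates all configurations (proper
#' rotations only, no reflections) to the evolving consensus until the
#' consensus changes by less than `tol` or `max_iter` iterations are
#' reached. The converged consensus is finally rotated to its principal
#' axes under a fixed sign convention, which makes the output independent
#' of the order in which specimens are supplied.
#'
#' @param configs List of [landmark_configuration()] objects with
#'   identical landmark count K.
#' @param tol Convergence tolerance on the consensus (root sum of squared
#'   change).
#' @param max_iter Maximum number of alignment sweeps.
#' @return An object of class `aligned_shape_set` with elements `shapes`
#'   (n x 3K matrix, rows flattened as x1,y1,z1,x2,...), `centroid_sizes`,
#'   `consensus` (length-3K vector), `metadata` (data.frame of specimen
#'   covariates), `k` (landmark count), `iterations`.
#' @export
generalized_procrustes <- function(configs, tol = 1e-10, max_iter = 100) {
  if (length(configs) < 2) stopf("need at least 2 configurations")
  stopifnot(all(vapply(configs, inherits, TRUE, "landmark_configuration")))
  ks <- vapply(configs, function(c) nrow(c$coords), 1L)
  if (length(unique(ks)) != 1) stopf("all configurations must share the same K")
  k <- ks[1]

  centered <- vector("list", length(configs))
  sizes <- numeric(length(configs))
  for (i in seq_along(configs)) {
    x <- configs[[i]]$coords
    x <- sweep(x, 2, colMeans(x))
    cs <- sqrt(sum(x^2))
    if (cs < 1e-12)
      stopf("degenerate configuration (coincident landmarks): specimen %s",
            configs[[i]]$specimen_id)
    sv <- svd(x)
    if (sv$d[2] < 1e-10 * sv$d[1])
      stopf("degenerate configuration (collinear landmarks): specimen %s",
            configs[[i]]$specimen_id)
    sizes[i] <- cs
    centered[[i]] <- x / cs
  }

  consensus <- centered[[1]]
  aligned <- centered
  iter <- 0
  repeat {
    iter <- iter + 1
    aligned <- lapply(centered, function(x) x %*% solve_rotation(x, consensus))
    new_consensus <- Reduce(`+`, aligned) / length(aligned)
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol || iter >= max_iter) break
  }

  # canonical orientation: rotate to the principal axes of the consensus,
  # then fix the sign of axes 1 and 2 by the consensus coordinate of
  # largest magnitude (axis 3's sign is forced by right-handedness, so
  # the whole map stays a proper rotation)
  sv <- svd(consensus)
  v <- sv$v
  v[, 3] <- c(v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
              v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
              v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2])
  rc <- consensus %*% v
  s1 <- sign(rc[which.max(abs(rc[, 1])), 1])
  s2 <- sign(rc[which.max(abs(rc[, 2])), 2])
  v <- v %*% diag(c(s1, s2, s1 * s2))
  aligned <- lapply(aligned, function(x) x %*% v)
  consensus <- consensus %*% v

  shapes <- do.call(rbind, lapply(aligned, flatten_shape))
  ids <- vapply(configs, function(c) c$specimen_id, "")
  rownames(shapes) <- ids
  metadata <- data.frame(
    specimen_id = ids,
    genotype = vapply(configs, function(c) as.character(c$genotype), ""),
    lab = vapply(configs, function(c) as.character(c$lab), ""),
    stage = vapply(configs, function(c) as.numeric(c$stage), 1),
    size_covariate = vapply(configs, function(c) as.numeric(c$size_covariate), 1),
    centroid_size = sizes,
    stringsAsFactors = FALSE)

  structure(list(shapes = shapes, centroid_sizes = sizes,
                 consensus = flatten_shape(consensus), metadata = metadata,
                 k = k, iterations = iter),
            class = "aligned_shape_set")
}

#' @export
print.aligned_shape_set <- function(x, ...) {
  cat(sprintf("Aligned shape set: %d specimens, %d landmarks (%d coordinates)\n",
              nrow(x$shapes), x$k, ncol(x$shapes)))
  cat(sprintf("  GPA converged in %d iteration(s)\n", x$iterations))
  gt <- table(x$metadata$genotype)
  if (length(gt) > 1)
    cat("  genotypes:", paste(sprintf("%s(%d)", names(gt), gt), collapse = ", "), "\n")
  invisible(x)
}

#' Procrustes distance between two shapes
#'
#' Rotation-optimal root-sum-of-squares distance between two flattened
#' configurations. Both are centered (and optionally scaled to unit
#' centroid size) before the optimal proper rotation is applied.
#'
#' @param a,b Length-3K shape vectors or K x 3 matrices.
#' @param scale Scale both to unit centroid size first (default TRUE).
#' @return Nonnegative distance.
#' @export
procrustes_distance <- function(a, b, scale = TRUE) {
  A <- if (is.matrix(a)) a else unflatten_shape(a)
  B <- if (is.matrix(b)) b else unflatten_shape(b)
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  if (scale) {
    A <- A / sqrt(sum(A^2)); B <- B / sqrt(sum(B^2))
  }
  r <- solve_rotation(A, B)
  sqrt(sum((A %*% r - B)^2))
}
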