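# Synthetic allelic-series generator: an ordered set of genotypes with
# graded mean expression, per-individual truncated-normal expression
# values, and 3D landmark configurations whose shape varies along one
# direction as a von Bertalanffy function of expression, contaminated
# with stage allometry, lab offsets, isotropic landmark noise, and
# nuisance rotation / translation / scale.

#' Genotype specification for a synthetic allelic series
#'
#' @param name Genotype label (unique within a series).
#' @param mean_expression Mean relative expression (1 = wild type),
#'   nonnegative.
#' @param expression_sd Within-genotype expression SD (> 0).
#' @param n_individuals Number of individuals (>= 1).
#' @param lab Lab (batch) label, or a vector of labels recycled across
#'   individuals (the wild-type group is typically split across labs so
#'   batch offsets can be estimated).
#' @param is_wild_type Flag marking the wild-type genotype.
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(name, mean_expression, expression_sd,
                          n_individuals, lab = "A", is_wild_type = FALSE) {
  if (!is_scalar_number(mean_expression) || mean_expression < 0)
    stopf("`mean_expression` must be nonnegative")
  if (!is_scalar_number(expression_sd) || expression_sd <= 0)
    stopf("`expression_sd` must be positive")
  if (n_individuals < 1) stopf("`n_individuals` must be at least 1")
  structure(list(name = as.character(name),
                 mean_expression = mean_expression,
                 expression_sd = expression_sd,
                 n_individuals = as.integer(n_individuals),
                 lab = as.character(lab),
                 is_wild_type = isTRUE(is_wild_type)),
            class = "genotype_spec")
}

#' Default allelic-series layout
#'
#' Nine genotypes spanning mean relative expression 0.14 to 1.1 of wild
#' type with homogeneous within-genotype SD, paired with the embryonic
#' sample sizes (27, 15, 30, 13, 16, 16, 19, 12, 8). Genotypes from the
#' two deletion strategies carry different lab labels; the wild-type
#' group is split across both labs.
#'
#' @return Numeric vector of genotype mean expressions.
#' @export
default_series_means <- function() {
  c(1.0, 1.1, 0.72, 0.56, 0.47, 0.42, 0.30, 0.22, 0.14)
}

#' @rdname default_series_means
#' @return Integer vector of per-genotype sample sizes.
#' @export
default_series_sizes <- function() {
  c(27L, 15L, 30L, 13L, 16L, 16L, 19L, 12L, 8L)
}

default_series_names <- function() {
  c("WT", "Flox/+", "Neo/+", "Flox/-", "Het",
    "Flox/+;Crect", "Flox/-;Crect", "Neo/Neo", "Neo/-")
}

default_series_labs <- function() {
  list(c("A", "B"), "A", "A", "A", "A", "B", "B", "A", "A")
}

# Orthonormal basis of the similarity-transform tangent space at a
# template (3 translations, 1 scaling, 3 infinitesimal rotations), used
# to build shape directions GPA cannot absorb.
similarity_basis <- function(template) {
  k <- nrow(template)
  p <- 3 * k
  basis <- matrix(0, p, 7)
  for (a in 1:3) basis[seq(a, p, by = 3), a] <- 1      # translations
  basis[, 4] <- flatten_shape(template)                 # scaling
  gens <- list(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE),
               matrix(c(0, 0, 1, 0, 0, 0, -1, 0, 0), 3, 3, byrow = TRUE),
               matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE))
  for (a in 1:3) basis[, 4 + a] <- flatten_shape(template %*% t(gens[[a]]))
  qr.Q(qr(basis))[, seq_len(qr(basis)$rank), drop = FALSE]
}

project_out_similarity <- function(v, template) {
  q <- similarity_basis(template)
  v - q %*% crossprod(q, v)
}

# Fixed 10-landmark 3D template (two asymmetric arcs), centered and
# scaled to unit centroid size. Deterministic: no RNG involved.
default_landmark_template <- function() {
  t1 <- seq(0, pi, length.out = 5)
  upper <- cbind(cos(t1), sin(t1), 0.30 + 0.08 * seq_len(5))
  lower <- cbind(0.8 * cos(t1 + 0.25), 0.55 * sin(t1 + 0.25) - 0.35,
                 -0.25 + 0.05 * (seq_len(5) %% 3))
  x <- rbind(upper, lower)
  x <- sweep(x, 2, colMeans(x))
  x / sqrt(sum(x^2))
}

# Deterministic unit direction in shape space, orthogonal to the
# similarity tangent space of the template.
default_shape_direction <- function(template, phase = 1.3) {
  p <- 3 * nrow(template)
  v <- sin(seq_len(p) * phase) + 0.5 * cos(seq_len(p) * (phase / 2 + 0.1))
  v <- project_out_similarity(v, template)
  as.vector(v / sqrt(sum(v^2)))
}

#' Configuration of a synthetic allelic series
#'
#' Bundles the genotype specifications, the generating G-P curve, the
#' landmark template and shape direction, and the nuisance-effect sizes.
#' Defaults emulate an embryonic allelic series: 9 genotypes with means
#' over 0.14 to 1.1, common expression SD 0.1, a unit-centroid-size
#' 10-landmark template, landmark noise SD 0.0015, a small fixed lab
#' offset, and a mild stage allometry over a tail-somite-like stage
#' covariate.
#'
#' @param genotypes List of [genotype_spec()] (exactly one spec per
#'   name; at least one wild type).
#' @param curve Generating [vb_params()].
#' @param landmark_template K x 3 mean shape (K >= 4).
#' @param shape_direction Unit vector of length 3K.
#' @param landmark_noise_sd Isotropic per-coordinate noise SD (> 0).
#' @param lab_offset Named list of length-3K offset vectors for each
#'   non-reference lab.
#' @param stage_allometry Length-3K shape change per unit of stage.
#' @param stage_range Range the uniform stage covariate is drawn from.
#' @param seed Integer seed driving all sampling from this config.
#' @return An object of class `series_config`.
#' @export
series_config <- function(genotypes = default_genotypes(),
                          curve = vb_params_e105(),
                          landmark_template = default_landmark_template(),
                          shape_direction = NULL,
                          landmark_noise_sd = 0.0015,
                          lab_offset = NULL,
                          stage_allometry = NULL,
                          stage_range = c(30, 36),
                          seed = 1L) {
  stopifnot(all(vapply(genotypes, inherits, TRUE, "genotype_spec")))
  nm <- vapply(genotypes, function(g) g$name, "")
  if (anyDuplicated(nm)) stopf("duplicate genotype names in series")
  template <- as.matrix(landmark_template)
  if (nrow(template) < 4) stopf("need at least 4 landmarks (K >= 4)")
  p <- 3 * nrow(template)
  if (is.null(shape_direction)) shape_direction <- default_shape_direction(template)
  if (abs(sqrt(sum(shape_direction^2)) - 1) > 1e-8)
    stopf("`shape_direction` must have unit norm")
  if (length(shape_direction) != p) stopf("`shape_direction` must have length 3K")
  if (!is_scalar_number(landmark_noise_sd) || landmark_noise_sd <= 0)
    stopf("`landmark_noise_sd` must be positive")
  if (is.null(lab_offset)) {
    off <- 0.01 * default_shape_direction(template, phase = 2.7)
    lab_offset <- list(B = off)
  }
  if (is.null(stage_allometry)) {
    stage_allometry <- 0.002 * default_shape_direction(template, phase = 0.9)
  }
  structure(list(genotypes = genotypes, curve = curve,
                 landmark_template = template,
                 shape_direction = as.vector(shape_direction),
                 landmark_noise_sd = landmark_noise_sd,
                 lab_offset = lab_offset,
                 stage_allometry = as.vector(stage_allometry),
                 stage_range = stage_range,
                 seed = as.integer(seed)),
            class = "series_config")
}

#' @rdname series_config
#' @param expression_sd Common within-genotype expression SD for the
#'   default genotype list.
#' @export
default_genotypes <- function(expression_sd = 0.1) {
  means <- default_series_means()
  sizes <- default_series_sizes()
  nms <- default_series_names()
  labs <- default_series_labs()
  Map(function(n, m, s, l, i)
    genotype_spec(n, m, expression_sd, s, lab = l, is_wild_type = i),
    nms, means, sizes, labs, c(TRUE, rep(FALSE, 8)))
}

#' Sample per-individual expression values for one genotype
#'
#' Draws `n_individuals` values from a normal distribution with the
#' genotype's mean and SD, truncated below at zero (expression cannot be
#' negative).
#'
#' @param spec A [genotype_spec()].
#' @param seed Integer seed (reproducible for a fixed seed).
#' @return Numeric vector of nonnegative expression values.
#' @export
sample_expression <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "genotype_spec"))
  with_seed(seed,
    rtruncnorm(spec$n_individuals,
               truncnorm_spec(spec$mean_expression, spec$expression_sd)))
}

# Uniform random proper rotation (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

#' Sample landmark configurations for a whole allelic series
#'
#' For each individual: shape = template + shape_direction * f(eps) +
#' stage_allometry * (stage - midpoint) + lab offset + iid Gaussian
#' coordinate noise, then an arbitrary rotation, translation, and
#' positive scale (log-uniform in [0.5, 2]) are applied. The returned
#' ground truth suffices to recompute every generated quantity.
#'
#' @param config A [series_config()].
#' @return A list with `configurations` (list of
#'   [landmark_configuration()]), `truth` (data.frame: specimen_id,
#'   genotype, lab, stage, expression, f_true), and `config`.
#' @export
sample_landmarks <- function(config) {
  stopifnot(inherits(config, "series_config"))
  template <- config$landmark_template
  tvec <- flatten_shape(template)
  mid_stage <- mean(config$stage_range)
  configs <- list()
  truth <- list()
  with_seed(config$seed, {
    for (g in config$genotypes) {
      eps <- rtruncnorm(g$n_individuals,
                        truncnorm_spec(g$mean_expression, g$expression_sd))
      f_true <- vb_eval(config$curve, eps)
      if (any(!is.finite(f_true))) stopf("curve evaluation non-finite")
      labs <- rep(g$lab, length.out = g$n_individuals)
      stages <- stats::runif(g$n_individuals, config$stage_range[1],
                             config$stage_range[2])
      for (i in seq_len(g$n_individuals)) {
        v <- tvec + config$shape_direction * f_true[i] +
          config$stage_allometry * (stages[i] - mid_stage)
        if (labs[i] %in% names(config$lab_offset))
          v <- v + config$lab_offset[[labs[i]]]
        x <- unflatten_shape(v) +
          matrix(stats::rnorm(length(v), 0, config$landmark_noise_sd), ncol = 3)
        x <- x %*% random_rotation()
        x <- x * exp(stats::runif(1, log(0.5), log(2)))
        x <- sweep(x, 2, stats::rnorm(3), `+`)
        id <- sprintf("%s_%02d", g$name, i)
        configs[[id]] <- landmark_configuration(
          x, id, genotype = g$name, lab = labs[i], stage = stages[i])
        truth[[id]] <- data.frame(
          specimen_id = id, genotype = g$name, lab = labs[i],
          stage = stages[i], expression = eps[i], f_true = f_true[i],
          stringsAsFactors = FALSE)
      }
    }
  })
  list(configurations = unname(configs),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       config = config)
}
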