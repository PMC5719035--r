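# Shape PCA, covariate standardization, lab-offset removal, shape
# regression, and Procrustes variance.

test_that("PCA concentrates one-directional variation on PC1", {
  set.seed(1)
  dir <- c(1, -2, 0.5, 3, -1, 0.25); dir <- dir / sqrt(sum(dir^2))
  x <- outer(rnorm(40), dir) + matrix(1, 40, 1) %*% t(rep(2, 6))
  pc <- shape_pca(x)
  expect_equal(pc$proportion[1], 1, tolerance = 1e-12)
  expect_equal(sum(pc$proportion), 1, tolerance = 1e-12)
})

test_that("PCA reproduces a hand-worked 2x2 eigendecomposition", {
  # construct data whose sample covariance is exactly [[2,1],[1,2]]
  s <- matrix(c(2, 1, 1, 2), 2)
  n <- 6
  set.seed(2)
  q <- qr.Q(qr(scale(matrix(rnorm(n * 2), n), scale = FALSE)))  # orthonormal, centered
  x <- sqrt(n - 1) * q %*% chol(s)
  expect_equal(stats::cov(x), s, tolerance = 1e-12)
  pc <- shape_pca(x)
  expect_equal(pc$eigenvalues, c(3, 1), tolerance = 1e-10)
  expect_equal(pc$proportion, c(0.75, 0.25), tolerance = 1e-10)
  # scores reproduce total variance
  expect_equal(sum(apply(pc$scores, 2, stats::var)), sum(diag(s)),
               tolerance = 1e-10)
})

test_that("PC1 orders a synthetic allelic series by expression", {
  sim <- sample_landmarks(series_config(seed = 21))
  g <- generalized_procrustes(sim$configurations)
  pc <- shape_pca(g)
  mean_pc1 <- tapply(pc$scores[, 1], g$metadata$genotype, mean)
  mean_eps <- tapply(sim$truth$expression, sim$truth$genotype, mean)
  rho <- stats::cor(mean_pc1, mean_eps[names(mean_pc1)], method = "spearman")
  expect_gt(abs(rho), 0.9)
})

test_that("standardization removes exactly the covariate's contribution", {
  sim <- sample_landmarks(small_series(noise_sd = 0.005, seed = 4))
  g <- generalized_procrustes(sim$configurations)
  std <- standardize_shapes(g, "stage")
  stage <- g$metadata$stage
  # residuals uncorrelated with the covariate, coordinate by coordinate
  cors <- abs(stats::cor(stage, std$shapes - rep(colMeans(std$shapes),
                                                 each = nrow(std$shapes))))
  expect_lt(max(cors), 1e-10)
  # covariate orthogonal to shape variation: output equals input
  set.seed(44)
  n <- 20
  t_score <- rnorm(n)
  d <- rnorm(6); d <- d / sqrt(sum(d^2))
  one_dir <- outer(t_score, d) + rep(1, n) %o% rnorm(6)
  u <- rnorm(n)
  u <- stats::resid(stats::lm(u ~ t_score))     # orthogonal to the scores
  fake <- structure(list(shapes = one_dir,
                         metadata = data.frame(stage = u)),
                    class = "aligned_shape_set")
  std2 <- standardize_shapes(fake, "stage")
  expect_lt(max(abs(std2$shapes - one_dir)), 1e-10)
  expect_error(standardize_shapes(g, rep(1, nrow(g$shapes))), "constant")
})

test_that("shapes built as mean + a*stage lose all variance along a after standardization", {
  set.seed(5)
  a <- rnorm(12); a <- a / sqrt(sum(a^2))
  stage <- seq(1, 4, length.out = 30)
  shapes <- outer(stage, a) + matrix(rnorm(30 * 12, 0, 0.01), 30)
  fake <- structure(list(shapes = shapes,
                         metadata = data.frame(stage = stage)),
                    class = "aligned_shape_set")
  std <- standardize_shapes(fake, "stage")
  # projection of residual variation onto a is pure noise, not the trend
  along_a <- std$shapes %*% a
  expect_lt(stats::var(along_a), 0.01^2 * 3)
})

test_that("lab offsets estimated from wild types are removed exactly", {
  cfg <- small_series(noise_sd = 1e-9, seed = 6)
  sim <- sample_landmarks(cfg)
  g <- generalized_procrustes(sim$configurations)
  wt <- "g100"
  adj <- remove_lab_offset(g, wt)
  md <- adj$metadata
  m_a <- colMeans(adj$shapes[md$genotype == wt & md$lab == "A", , drop = FALSE])
  m_b <- colMeans(adj$shapes[md$genotype == wt & md$lab == "B", , drop = FALSE])
  expect_lt(max(abs(m_a - m_b)), 1e-10)
  expect_error(remove_lab_offset(g, "g40"), "no wild-type")
  # identical labs: removing offsets is a no-op
  g2 <- g; g2$metadata$lab <- "A"
  expect_equal(remove_lab_offset(g2, wt)$shapes, g$shapes)
})

test_that("shape regression is exact for noiseless linear data", {
  set.seed(7)
  d <- rnorm(9)
  x <- runif(25)
  shapes <- outer(x, d) + rep(1, 25) %o% rnorm(9)
  fit <- shape_regression(shapes, x)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # scores reproduce the covariate up to an affine map
  expect_gt(abs(stats::cor(fit$regression_scores, x)), 1 - 1e-10)
})

test_that("shape regression matches an explicit normal-equations oracle", {
  set.seed(8)
  n <- 100; p <- 6
  shapes <- matrix(rnorm(n * p), n)
  x <- rnorm(n)
  fit <- shape_regression(shapes, x)
  xc <- x - mean(x)
  yc <- scale(shapes, scale = FALSE)
  beta <- as.vector(t(yc) %*% xc / sum(xc^2))
  expect_equal(fit$coefficients, beta, tolerance = 1e-12)
  ss_fit <- sum(outer(xc, beta)^2)
  expect_equal(fit$r_squared, ss_fit / sum(yc^2), tolerance = 1e-12)
  # pure noise: r_squared on the 1/(n-1) scale
  expect_lt(fit$r_squared, 10 / (n - 1))
  # r_squared + residual fraction = 1
  resid_frac <- sum((fit$residual_shapes -
                       rep(colMeans(shapes), each = n))^2) / sum(yc^2)
  expect_equal(fit$r_squared + resid_frac, 1, tolerance = 1e-12)
})

test_that("Procrustes variance follows two-point algebra and shift invariance", {
  x <- rbind(c(0, 0, 0, 0), c(1, 1, 0, 0))
  d <- sqrt(sum((x[1, ] - x[2, ])^2))
  # each point deviates d/2 from the mean: sum of squares d^2/2, so the
  # population (divisor n = 2) disparity is d^2/4 and the sample
  # (divisor n-1 = 1) disparity is d^2/2
  pv <- procrustes_variance(x, c("a", "a"))
  expect_equal(pv$disparity, d^2 / 4)
  pv2 <- procrustes_variance(x, c("a", "a"), divisor = "n-1")
  expect_equal(pv2$disparity, d^2 / 2)
  # identical shapes: zero disparity
  same <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(procrustes_variance(same, rep("g", 3))$disparity, 0)
  # adding a constant vector to a group leaves its disparity unchanged
  set.seed(9)
  y <- matrix(rnorm(30), 10)
  shifted <- sweep(y, 2, c(5, -2, 7), `+`)
  expect_equal(procrustes_variance(y, rep("g", 10))$disparity,
               procrustes_variance(shifted, rep("g", 10))$disparity,
               tolerance = 1e-12)
  # singleton groups are flagged, not silently averaged
  pv3 <- procrustes_variance(y, c(rep("a", 9), "b"))
  expect_false(pv3$defined[pv3$group == "b"])
  expect_true(is.na(pv3$disparity[pv3$group == "b"]))
})
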