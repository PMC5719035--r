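# Shared fixtures built in code: tiny landmark sets, small series
# configurations, and reference curve parameter sets.

e105 <- gpcurve::vb_params_e105()
p0 <- gpcurve::vb_params_p0()

# A unit right triangle embedded in 3D (z = 0); rank 2, non-degenerate.
unit_triangle <- function() {
  matrix(c(0, 0, 0,
           1, 0, 0,
           0, 1, 0), ncol = 3, byrow = TRUE)
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

random_rigid <- function(coords) {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  s <- exp(stats::runif(1, log(0.5), log(2)))
  sweep(coords %*% q * s, 2, stats::rnorm(3), `+`)
}

# Small series: fewer genotypes / individuals for fast tests.
small_series <- function(noise_sd = 1e-9, seed = 1, expression_sd = 0.05,
                         means = c(1.0, 0.4, 0.15), n = c(8, 8, 8),
                         labs = list(c("A", "B"), "A", "B"), ...) {
  gts <- Map(function(m, nn, l, i)
    gpcurve::genotype_spec(paste0("g", round(100 * m)), m, expression_sd, nn,
                           lab = l, is_wild_type = i),
    means, n, labs, c(TRUE, rep(FALSE, length(means) - 1)))
  gpcurve::series_config(genotypes = gts, landmark_noise_sd = noise_sd,
                         seed = seed, ...)
}
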