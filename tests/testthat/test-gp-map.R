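# von Bertalanffy curve, truncated-normal machinery, and the variance
# propagation (mean phenotype, sensitivity, predicted variance).

test_that("curve evaluation reproduces the reported parameter sets", {
  expect_equal(vb_eval(e105, 0), -0.12787)
  # high-precision evaluation of the P0 formula at eps = 0.4
  oracle <- 0.0288 - (0.0288 - (-1.333)) * exp(-13.049 * 0.4)
  expect_equal(vb_eval(p0, 0.4), oracle, tolerance = 1e-12)
  expect_equal(round(vb_eval(p0, 0.4), 5), 0.02143)
  # asymptote
  expect_equal(vb_eval(e105, 1e6), e105$L_m, tolerance = 1e-12)
  expect_error(vb_eval(e105, -0.1), "nonnegative")
})

test_that("derivative matches a central finite difference and decays", {
  h <- 1e-6
  for (p in list(e105, p0)) {
    for (eps in c(0, 0.14, 0.5, 1)) {
      fd <- (vb_eval(p, eps + h) - vb_eval(p, max(eps - h, 0))) /
        (h + min(eps, h))
      expect_equal(vb_derivative(p, eps), fd, tolerance = 1e-5)
    }
    expect_equal(vb_derivative(p, 0), p$k * (p$L_m - p$L_0))
    # slopes are much larger below the threshold than at wild type
    expect_gt(vb_derivative(p, 0.14), vb_derivative(p, 1.0))
  }
})

test_that("truncated-normal moments match closed forms", {
  # negligible truncation far from the bound
  m5 <- truncnorm_moments(truncnorm_spec(5, 1))
  expect_equal(m5$mean, 5, tolerance = 1e-6)
  expect_equal(m5$var, 1, tolerance = 1e-5)
  # half-normal
  m0 <- truncnorm_moments(truncnorm_spec(0, 1))
  expect_equal(m0$mean, sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(m0$var, 1 - 2 / pi, tolerance = 1e-12)
  expect_identical(m0$mgf(0), 1)
  # MGF stays finite at large negative arguments (needed for M(-2k), P0)
  expect_true(is.finite(truncnorm_moments(truncnorm_spec(0.2, 0.5))$mgf(-30)))
})

test_that("predicted mean collapses to f(mean) as sd -> 0 and obeys Jensen", {
  spec <- truncnorm_spec(0.6, 1e-4)
  expect_equal(predicted_mean(e105, spec), vb_eval(e105, 0.6),
               tolerance = 1e-6)
  # linearity oracle: linear f propagates exactly through the mean
  lin <- linear_map(0.3, -0.7)
  s <- truncnorm_spec(0.2, 0.15)
  expect_equal(predicted_mean(lin, s),
               0.3 - 0.7 * truncnorm_moments(s)$mean, tolerance = 1e-12)
  # concave saturating curve: E[f(eps)] < f(E[eps]) strictly
  s1 <- truncnorm_spec(1, 0.1)
  expect_lt(predicted_mean(e105, s1), vb_eval(e105, 1))
})

test_that("sensitivity is the expected slope and tracks the curve", {
  lin <- linear_map(2, 0.42)
  expect_equal(sensitivity_phi(lin, truncnorm_spec(0.5, 0.2)), 0.42)
  spec <- truncnorm_spec(0.7, 1e-4)
  expect_equal(sensitivity_phi(e105, spec), vb_derivative(e105, 0.7),
               tolerance = 1e-6)
  # sensitivity rises as mean expression falls (the robustness gradient)
  expect_gt(sensitivity_phi(e105, truncnorm_spec(0.2, 0.1)),
            sensitivity_phi(e105, truncnorm_spec(1.0, 0.1)))
})

test_that("variance propagation is exact for linear maps and vanishes at sd -> 0", {
  lin <- linear_map(-1, 1.7)
  for (m in c(0, 0.3, 1)) {
    s <- truncnorm_spec(m, 0.2)
    v1 <- predicted_variance(lin, s, "first_order")
    v2 <- predicted_variance(lin, s, "exact")
    expect_equal(v1, 1.7^2 * truncnorm_moments(s)$var, tolerance = 1e-10)
    expect_equal(v1, v2, tolerance = 1e-8)
  }
  tiny <- truncnorm_spec(0.5, 1e-6)
  expect_lt(predicted_variance(e105, tiny, "first_order"), 1e-10)
  expect_lt(predicted_variance(e105, tiny, "exact"), 1e-10)
})

test_that("exact predicted variance matches Monte Carlo", {
  spec <- truncnorm_spec(0.3, 0.1)
  v_exact <- predicted_variance(e105, spec, "exact")
  n <- 1e5
  draws <- gpcurve:::with_seed(42, gpcurve:::rtruncnorm(n, spec))
  fz <- vb_eval(e105, draws)
  v_mc <- stats::var(fz)
  se <- v_mc * sqrt(2 / (n - 1))   # chi-square SE of a variance estimate
  expect_lt(abs(v_mc - v_exact), 3 * se)
})

test_that("variance response surface is self-consistent and near-flat at high expression", {
  surf <- variance_response_surface(e105, means = c(0.2, 0.6, 1.0),
                                    sds = c(0.05, 0.1, 0.2))
  for (i in seq_len(nrow(surf))) {
    s <- truncnorm_spec(surf$mean_expression[i], surf$sd_expression[i])
    expect_equal(surf$var_exact[i], predicted_variance(e105, s, "exact"),
                 tolerance = 1e-12)
    expect_equal(surf$var_first_order[i],
                 predicted_variance(e105, s, "first_order"),
                 tolerance = 1e-12)
  }
  # above half of wild-type expression, phenotypic SD barely responds to
  # expression SD; at low expression it responds strongly
  hi <- surf[surf$mean_expression == 1.0, ]
  lo <- surf[surf$mean_expression == 0.2, ]
  expect_lt(max(hi$sd_exact), 0.1 * max(lo$sd_exact))
  # predicted variance strictly decreasing in mean expression at fixed sd
  fixed <- surf[surf$sd_expression == 0.1, ]
  expect_true(all(diff(fixed$var_exact[order(fixed$mean_expression)]) < 0))
})

test_that("noiseless curve fits recover the generating parameters", {
  for (p in list(e105, p0)) {
    eps <- seq(0.05, 1.2, length.out = 20)
    z <- vb_eval(p, eps)
    fit <- fit_vb(eps, z)
    expect_true(fit$converged)
    expect_equal(fit$params$L_m, p$L_m, tolerance = 1e-6)
    expect_equal(fit$params$L_0, p$L_0, tolerance = 1e-6)
    expect_equal(fit$params$k, p$k, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("degenerate (linear) data is flagged rather than silently fit", {
  eps <- seq(0, 1, length.out = 12)
  z <- 0.2 + 0.5 * eps            # k -> 0 limit of the curve family
  fit <- fit_vb(eps, z)
  expect_true(fit$boundary || !fit$converged)
})

test_that("threshold expression has its closed form and monotonicity", {
  expect_equal(threshold_expression(e105, 1), 0)
  expect_equal(threshold_expression(e105, 0.1), log(10) / 5.3003,
               tolerance = 1e-12)
  expect_equal(round(threshold_expression(e105, 0.1), 4), 0.4344)
  k_grid <- c(2, 5, 13)
  eps_star <- vapply(k_grid, function(k)
    threshold_expression(vb_params(0, -1, k), 0.1), 1.0)
  expect_true(all(diff(eps_star) < 0))
})
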