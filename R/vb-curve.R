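#' von Bertalanffy genotype-phenotype curve parameters
#'
#' The saturating curve `z = L_m - (L_m - L_0) * exp(-k * eps)` relating a
#' developmental quantity `eps` (relative expression, 1 = wild type) to a
#' one-dimensional phenotype score `z`. `L_m` is the asymptotic phenotype,
#' `L_0` the phenotype at zero expression, and `k` a rate constant giving
#' the proportional decrease in slope per unit of expression.
#'
#' @param L_m Asymptotic phenotype (regression-score units).
#' @param L_0 Phenotype at zero expression.
#' @param k Rate constant; must be positive.
#' @return An object of class `vb_params`.
#' @examples
#' ## curve for the E10.5 embryo data
#' p <- vb_params(0.01765, -0.12787, 5.3003)
#' vb_eval(p, c(0, 0.4, 1))
#' @export
vb_params <- function(L_m, L_0, k) {
  if (!is_scalar_number(L_m) || !is_scalar_number(L_0))
    stopf("`L_m` and `L_0` must be finite numbers")
  if (!is_scalar_number(k) || k <= 0) stopf("`k` must be a positive number")
  structure(list(L_m = L_m, L_0 = L_0, k = k), class = "vb_params")
}

#' @export
print.vb_params <- function(x, ...) {
  cat(sprintf("von Bertalanffy G-P curve: z = %.5g - (%.5g - (%.5g)) * exp(-%.5g * eps)\n",
              x$L_m, x$L_m, x$L_0, x$k))
  invisible(x)
}

#' Evaluate a von Bertalanffy curve
#'
#' @param params A [vb_params()] or [linear_map()] object.
#' @param eps Vector of nonnegative expression values.
#' @return Phenotype values `f(eps)`.
#' @export
vb_eval <- function(params, eps) {
  if (any(eps < 0)) stopf("expression values must be nonnegative")
  UseMethod("vb_eval")
}

#' @export
vb_eval.vb_params <- function(params, eps) {
  params$L_m - (params$L_m - params$L_0) * exp(-params$k * eps)
}

#' First derivative of the genotype-phenotype curve
#'
#' `f'(eps) = k * (L_m - L_0) * exp(-k * eps)`, the local sensitivity of
#' phenotype to expression.
#'
#' @inheritParams vb_eval
#' @return Slope values `f'(eps)`.
#' @export
vb_derivative <- function(params, eps) {
  if (any(eps < 0)) stopf("expression values must be nonnegative")
  UseMethod("vb_derivative")
}

#' @export
vb_derivative.vb_params <- function(params, eps) {
  params$k * (params$L_m - params$L_0) * exp(-params$k * eps)
}

#' Linear genotype-phenotype map
#'
#' `f(eps) = a + b * eps`. For a linear map the variance propagation is
#' exact, which makes this the natural control against which the
#' first-order approximation is validated.
#'
#' @param a Intercept.
#' @param b Slope.
#' @return An object of classes `linear_map` and `gp_map`.
#' @export
linear_map <- function(a, b) {
  if (!is_scalar_number(a) || !is_scalar_number(b))
    stopf("`a` and `b` must be finite numbers")
  structure(list(a = a, b = b), class = c("linear_map"))
}

#' @export
vb_eval.linear_map <- function(params, eps) params$a + params$b * eps

#' @export
vb_derivative.linear_map <- function(params, eps) rep(params$b, length(eps))

#' Expression level at which the curve flattens
#'
#' Smallest expression `eps*` at which the slope has fallen to
#' `slope_fraction` of its value at zero expression; in closed form
#' `eps* = log(1/slope_fraction) / k`. Operationalizes the apparent
#' threshold below which small expression differences have large
#' phenotypic effects.
#'
#' @param params A [vb_params()].
#' @param slope_fraction Fraction in (0, 1].
#' @return The threshold expression level.
#' @export
threshold_expression <- function(params, slope_fraction) {
  stopifnot(inherits(params, "vb_params"))
  if (!is_scalar_number(slope_fraction) || slope_fraction <= 0 || slope_fraction > 1)
    stopf("`slope_fraction` must lie in (0, 1]")
  log(1 / slope_fraction) / params$k
}

#' Fit a von Bertalanffy curve by nonlinear least squares
#'
#' Minimizes `sum((z - f(eps))^2)` over `(L_m, L_0, k)` by
#' Levenberg-Marquardt. Starting values default to `L_m = max(z)`,
#' `L_0 = min(z)`, and a small grid of rate constants
#' `k in {0.5, 1, 5, 50}` (the sum of squares is multimodal in `k` for
#' noisy data); the restart with the lowest residual sum of squares wins.
#'
#' @param expression Nonnegative expression values (length >= 4,
#'   non-constant).
#' @param phenotype Phenotype scores, same length.
#' @param starts Optional named list/vector with elements `L_m`, `L_0`,
#'   `k` used as the only start.
#' @param k_max Upper bound on `k`; fits driven to within 1% of a bound
#'   are flagged (`boundary = TRUE`).
#' @return An object of class `vb_fit`: `params` ([vb_params()]),
#'   `residual_ss`, `r_squared`, `converged`, `boundary`, `n_used`,
#'   `fitted`, `residuals`.
#' @export
fit_vb <- function(expression, phenotype, starts = NULL, k_max = 1e3) {
  if (length(expression) != length(phenotype))
    stopf("`expression` and `phenotype` must have the same length")
  keep <- is.finite(expression) & is.finite(phenotype)
  x <- expression[keep]; z <- phenotype[keep]
  if (length(x) < 4) stopf("need at least 4 complete observations")
  if (any(x < 0)) stopf("expression values must be nonnegative")
  if (stats::sd(x) == 0) stopf("expression values are constant")

  k_min <- 1e-6
  start_list <- if (!is.null(starts)) {
    list(as.list(starts[c("L_m", "L_0", "k")]))
  } else {
    lapply(c(1, 0.5, 5, 50), function(k0)
      list(L_m = max(z), L_0 = min(z), k = k0))
  }

  best <- NULL
  for (s0 in start_list) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        z ~ L_m - (L_m - L_0) * exp(-k * x),
        start = list(L_m = s0$L_m, L_0 = s0$L_0, k = s0$k),
        lower = c(-Inf, -Inf, k_min), upper = c(Inf, Inf, k_max),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(structure(list(params = NULL, residual_ss = NA_real_,
                          r_squared = NA_real_, converged = FALSE,
                          boundary = FALSE, n_used = length(x),
                          fitted = NULL, residuals = NULL),
                     class = "vb_fit"))

  co <- stats::coef(best$fit)
  k_hat <- unname(co["k"])
  boundary <- k_hat <= k_min * 100 || k_hat >= k_max * 0.99
  tss <- sum((z - mean(z))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - best$rss / tss)) else NA_real_
  structure(list(
    params = vb_params(unname(co["L_m"]), unname(co["L_0"]), max(k_hat, k_min)),
    residual_ss = best$rss,
    r_squared = r2,
    converged = best$fit$convInfo$isConv && !boundary,
    boundary = boundary,
    n_used = length(x),
    fitted = stats::fitted(best$fit),
    residuals = stats::resid(best$fit)
  ), class = "vb_fit")
}

#' @export
print.vb_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("von Bertalanffy fit: FAILED to converge\n")
    return(invisible(x))
  }
  cat("von Bertalanffy nonlinear least-squares fit\n")
  cat(sprintf("  L_m = %.5g, L_0 = %.5g, k = %.4g\n",
              x$params$L_m, x$params$L_0, x$params$k))
  cat(sprintf("  n = %d, RSS = %.4g, R^2 = %.3f%s\n", x$n_used,
              x$residual_ss, x$r_squared,
              if (!x$converged) "  [not converged / boundary]" else ""))
  invisible(x)
}

#' Parameter-recovery experiment for the G-P curve fit
#'
#' Simulates an allelic series from a known curve and refits it, repeated
#' over independent seeds. For each replicate, per-individual expression
#' values are drawn from truncated normals around the series' genotype
#' means, phenotype scores are the curve values plus Gaussian noise whose
#' standard deviation is `noise_frac` of the curve range `|L_m - L_0|`,
#' and [fit_vb()] is refit to the pooled individuals.
#'
#' @param true_params Generating [vb_params()].
#' @param genotype_means Mean relative expression per genotype.
#' @param n_per_genotype Individuals per genotype.
#' @param expression_sd Common within-genotype expression SD.
#' @param noise_frac Phenotype noise SD as a fraction of the curve range.
#' @param n_seeds Number of independent replicates.
#' @param seed Base seed; replicate `i` uses `seed + i`.
#' @return A list with `estimates` (data.frame of L_m, L_0, k per seed),
#'   `means` (averaged estimates), `true` (the generating parameters) and
#'   `n` (individuals per replicate).
#' @export
vb_recovery_experiment <- function(true_params,
                                   genotype_means = default_series_means(),
                                   n_per_genotype = default_series_sizes(),
                                   expression_sd = 0.1,
                                   noise_frac = 0.05,
                                   n_seeds = 20,
                                   seed = 1) {
  stopifnot(inherits(true_params, "vb_params"))
  stopifnot(length(genotype_means) == length(n_per_genotype))
  noise_sd <- noise_frac * abs(true_params$L_m - true_params$L_0)
  est <- vapply(seq_len(n_seeds), function(i) {
    with_seed(seed + i, {
      eps <- unlist(Map(function(m, n)
        rtruncnorm(n, truncnorm_spec(m, expression_sd)),
        genotype_means, n_per_genotype))
      z <- vb_eval(true_params, eps) + stats::rnorm(length(eps), 0, noise_sd)
      fit <- fit_vb(eps, z)
      c(fit$params$L_m, fit$params$L_0, fit$params$k)
    })
  }, numeric(3))
  estimates <- data.frame(seed = seed + seq_len(n_seeds),
                          L_m = est[1, ], L_0 = est[2, ], k = est[3, ])
  list(estimates = estimates,
       means = c(L_m = mean(est[1, ]), L_0 = mean(est[2, ]), k = mean(est[3, ])),
       true = true_params,
       n = sum(n_per_genotype))
}

#' Published curve parameter sets
#'
#' Convenience constructors for the two fitted curves reported for the
#' embryonic (E10.5) and neonatal (P0) craniofacial data.
#' @return A [vb_params()] object.
#' @export
vb_params_e105 <- function() vb_params(0.01765, -0.12787, 5.3003)

#' @rdname vb_params_e105
#' @export
vb_params_p0 <- function() vb_params(0.0288, -1.333, 13.049)
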