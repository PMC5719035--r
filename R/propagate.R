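# Propagation of developmental variance through the G-P curve:
# mean phenotype as the integral of f against the expression distribution,
# sensitivity Phi as the integral of f', and phenotypic variance either to
# first order (Phi^2 * Var[eps]) or exactly (Var[f(eps)]).

# Adaptive quadrature of g(eps) * p(eps) over the 10-sigma window where
# the truncated density has its mass (so narrow spikes are not missed).
.quad_expect <- function(g, spec, abs.tol = 1e-10) {
  upper <- max(spec$mean, spec$lower) + 10 * spec$sd
  lower <- max(spec$lower, spec$mean - 10 * spec$sd)
  res <- tryCatch(
    stats::integrate(function(e) g(e) * dtruncnorm(e, spec),
                     lower = lower, upper = upper,
                     abs.tol = abs.tol, rel.tol = 1e-10,
                     subdivisions = 500L),
    error = function(e) stopf("quadrature failed: %s", conditionMessage(e)))
  res$value
}

#' Predicted mean phenotype under a distribution of developmental values
#'
#' Computes `zbar = E[f(eps)]` for the G-P curve `f` with `eps` following
#' the truncated-normal distribution `spec`. Evaluated two ways -- adaptive
#' quadrature of `f * density`, and the closed form
#' `L_m - (L_m - L_0) * M(-k)` via the truncated-normal moment generating
#' function -- and cross-checked to 1e-8; disagreement is an error.
#'
#' @param params A [vb_params()] or [linear_map()].
#' @param spec A [truncnorm_spec()] for the expression distribution.
#' @return The predicted mean phenotype (scalar).
#' @export
predicted_mean <- function(params, spec) {
  stopifnot(inherits(spec, "truncnorm_spec"))
  mom <- truncnorm_moments(spec)
  closed <- if (inherits(params, "vb_params")) {
    params$L_m - (params$L_m - params$L_0) * mom$mgf(-params$k)
  } else if (inherits(params, "linear_map")) {
    params$a + params$b * mom$mean
  } else stopf("unsupported curve object")
  quad <- .quad_expect(function(e) vb_eval(params, e), spec)
  if (abs(quad - closed) > 1e-8)
    stopf("quadrature (%.12g) and closed form (%.12g) disagree", quad, closed)
  closed
}

#' Mean sensitivity of phenotype to expression
#'
#' `Phi = E[f'(eps)]`, the expected slope of the G-P curve over the
#' expression distribution; in closed form
#' `k * (L_m - L_0) * M(-k)`. Quadrature and closed form are
#' cross-checked to 1e-8.
#'
#' @inheritParams predicted_mean
#' @return The sensitivity `Phi` (scalar).
#' @export
sensitivity_phi <- function(params, spec) {
  stopifnot(inherits(spec, "truncnorm_spec"))
  mom <- truncnorm_moments(spec)
  closed <- if (inherits(params, "vb_params")) {
    params$k * (params$L_m - params$L_0) * mom$mgf(-params$k)
  } else if (inherits(params, "linear_map")) {
    params$b
  } else stopf("unsupported curve object")
  quad <- .quad_expect(function(e) vb_derivative(params, e), spec)
  if (abs(quad - closed) > 1e-8)
    stopf("quadrature (%.12g) and closed form (%.12g) disagree", quad, closed)
  closed
}

#' Predicted phenotypic variance
#'
#' First-order propagation `sigma_z^2 = Phi^2 * Var[eps]` (with `Var[eps]`
#' the variance of the truncated expression distribution, so the formula
#' is exact for linear maps), or the exact variance
#' `Var[f(eps)] = E[f(eps)^2] - E[f(eps)]^2` by quadrature.
#'
#' @inheritParams predicted_mean
#' @param method `"first_order"` or `"exact"`.
#' @return Nonnegative predicted variance (scalar).
#' @export
predicted_variance <- function(params, spec,
                               method = c("first_order", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "truncnorm_spec"))
  mom <- truncnorm_moments(spec)
  if (method == "first_order") {
    phi <- sensitivity_phi(params, spec)
    return(phi^2 * mom$var)
  }
  zbar <- predicted_mean(params, spec)
  if (inherits(params, "vb_params")) {
    # E[f^2] in closed form through M(-k) and M(-2k); quadrature cross-check
    d <- params$L_m - params$L_0
    ef2 <- params$L_m^2 - 2 * params$L_m * d * mom$mgf(-params$k) +
      d^2 * mom$mgf(-2 * params$k)
    quad <- .quad_expect(function(e) vb_eval(params, e)^2, spec)
    if (abs(quad - ef2) > 1e-8 * max(1, abs(ef2)))
      stopf("exact-variance quadrature and closed form disagree")
  } else {
    ef2 <- .quad_expect(function(e) vb_eval(params, e)^2, spec)
  }
  max(ef2 - zbar^2, 0)
}

#' Predicted-variance response surface
#'
#' Evaluates the predicted phenotypic mean and variance over a grid of
#' expression means and standard deviations, mirroring the model's
#' predicted relationship between expression variance and phenotypic
#' variance at different mean expression levels. Truncation at zero bends
#' the low-mean rows away from simple proportionality in `sds`.
#'
#' @param params A [vb_params()] or [linear_map()].
#' @param means Grid of expression means (nonnegative).
#' @param sds Grid of expression SDs (positive).
#' @return A data.frame with one row per (mean, sd) combination:
#'   `mean_expression`, `sd_expression`, `mean_phenotype`, `sensitivity`,
#'   `var_first_order`, `var_exact`, `sd_first_order`, `sd_exact`.
#' @export
variance_response_surface <- function(params, means, sds) {
  if (any(means < 0) || any(sds <= 0))
    stopf("`means` must be nonnegative and `sds` positive")
  grid <- expand.grid(mean_expression = means, sd_expression = sds,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- truncnorm_spec(grid$mean_expression[i], grid$sd_expression[i])
    v1 <- predicted_variance(params, spec, "first_order")
    v2 <- predicted_variance(params, spec, "exact")
    data.frame(mean_expression = grid$mean_expression[i],
               sd_expression = grid$sd_expression[i],
               mean_phenotype = predicted_mean(params, spec),
               sensitivity = sensitivity_phi(params, spec),
               var_first_order = v1, var_exact = v2,
               sd_first_order = sqrt(v1), sd_exact = sqrt(v2))
  })
  do.call(rbind, rows)
}
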