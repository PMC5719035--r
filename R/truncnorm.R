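#' Truncated-normal distribution of developmental values
#'
#' Specifies the distribution of a developmental quantity (here, relative
#' gene expression) as a normal distribution with mean `mean` and standard
#' deviation `sd`, truncated below at `lower`. Expression cannot be
#' negative, so the truncation bound defaults to 0 and the upper bound is
#' +Inf.
#'
#' @param mean Mean of the untruncated (parent) normal, in relative
#'   expression units (1 = wild type).
#' @param sd Standard deviation of the parent normal; must be positive.
#' @param lower Lower truncation bound; defaults to 0.
#' @return An object of class `truncnorm_spec`.
#' @examples
#' spec <- truncnorm_spec(0.3, 0.1)
#' truncnorm_moments(spec)$mean
#' @export
truncnorm_spec <- function(mean, sd, lower = 0) {
  if (!is_scalar_number(mean)) stopf("`mean` must be a finite number")
  if (!is_scalar_number(sd) || sd <= 0) stopf("`sd` must be a positive number")
  if (!is_scalar_number(lower)) stopf("`lower` must be a finite number")
  structure(list(mean = mean, sd = sd, lower = lower),
            class = "truncnorm_spec")
}

#' Moments and exponential-moment evaluator of a truncated normal
#'
#' Closed-form mean and variance of the lower-truncated normal, plus the
#' moment generating function `M(t) = E[exp(t * eps)]`, evaluated on the
#' log scale for numerical stability at large `|t|`.
#'
#' With `xi = (lower - mean)/sd` and `Z = 1 - pnorm(xi)`:
#' mean is `mean + sd * dnorm(xi)/Z`, variance is
#' `sd^2 * (1 + xi*dnorm(xi)/Z - (dnorm(xi)/Z)^2)`, and
#' `M(t) = exp(mean*t + sd^2 t^2/2) * (1 - pnorm(xi - sd*t)) / Z`.
#'
#' @param spec A [truncnorm_spec()].
#' @return A list with elements `mean`, `var`, `sd`, and `mgf` (a
#'   vectorized function of `t`; `mgf(0)` is exactly 1).
#' @export
truncnorm_moments <- function(spec) {
  stopifnot(inherits(spec, "truncnorm_spec"))
  mu <- spec$mean; s <- spec$sd; a <- spec$lower
  xi <- (a - mu) / s
  logZ <- stats::pnorm(xi, lower.tail = FALSE, log.p = TRUE)
  lambda <- exp(stats::dnorm(xi, log = TRUE) - logZ)  # hazard dnorm(xi)/Z
  m <- mu + s * lambda
  v <- s^2 * (1 + xi * lambda - lambda^2)
  mgf <- function(t) {
    log_tail <- stats::pnorm(xi - s * t, lower.tail = FALSE, log.p = TRUE)
    exp(mu * t + 0.5 * s^2 * t^2 + log_tail - logZ)
  }
  list(mean = m, var = max(v, 0), sd = sqrt(max(v, 0)), mgf = mgf)
}

# Density of the truncated normal (vectorized; 0 below the bound).
dtruncnorm <- function(x, spec) {
  xi <- (spec$lower - spec$mean) / spec$sd
  logZ <- stats::pnorm(xi, lower.tail = FALSE, log.p = TRUE)
  out <- ifelse(x < spec$lower, 0,
                stats::dnorm(x, spec$mean, spec$sd) / exp(logZ))
  out
}

# Inverse-CDF sampler for the truncated normal.
rtruncnorm <- function(n, spec) {
  p0 <- stats::pnorm(spec$lower, spec$mean, spec$sd)
  u <- p0 + stats::runif(n) * (1 - p0)
  q <- stats::qnorm(u, spec$mean, spec$sd)
  pmax(q, spec$lower)  # guard against rounding at the bound
}
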