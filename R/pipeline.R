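# End-to-end analysis: simulate (or ingest) an allelic series, align and
# standardize shapes, fit the G-P curve to regression scores, propagate
# expression variance through the fitted curve, and compare predicted
# with observed per-genotype shape variance.

#' Run the full robustness analysis on an allelic series
#'
#' Pipeline order: generalized Procrustes analysis, lab-offset removal,
#' stage standardization, multivariate regression of shape on expression
#' (yielding regression scores), von Bertalanffy curve fit, variance
#' propagation per genotype, and observed disparity with optional
#' pairwise permutation tests. With `landmarks = NULL` the series is
#' simulated from `config`; measured expression defaults to the
#' generator's per-individual ground truth.
#'
#' @param config A [series_config()].
#' @param landmarks Optional list of [landmark_configuration()] to
#'   analyse instead of simulating; requires `expression`.
#' @param expression Optional per-specimen expression values (same order
#'   as `landmarks`).
#' @param n_perm Permutations for the pairwise disparity test; 0 skips
#'   the test.
#' @param seed Seed for the permutation test (defaults to the config
#'   seed).
#' @param curve_fit Fit the curve to `"individual"` points (default) or
#'   to `"genotype_mean"` (one point per genotype).
#' @param slope_fraction Slope fraction defining the reported threshold
#'   expression level.
#' @param standardize_on Metadata column regressed out before analysis
#'   (`"stage"` for embryos, `"centroid_size"` for neonates); `NULL`
#'   skips standardization.
#' @param out_dir Optional directory: aligned shapes, scores, the
#'   per-genotype report and test tables are written there as CSV/YAML.
#' @return An object of class `robustness_report`: `per_genotype`
#'   (data.frame), `fit` ([fit_vb()] result), `regression`
#'   (r-squared of shape on expression), `threshold`,
#'   `spearman_predicted_observed`, `expression_tests` (Levene + ANOVA),
#'   `disparity_p` (matrix or NULL), `aligned`, `scores`, `expression`.
#' @export
run_pipeline <- function(config = series_config(), landmarks = NULL,
                         expression = NULL, n_perm = 999, seed = NULL,
                         curve_fit = c("individual", "genotype_mean"),
                         slope_fraction = 0.1,
                         standardize_on = "stage", out_dir = NULL) {
  curve_fit <- match.arg(curve_fit)
  if (is.null(seed)) seed <- config$seed

  if (is.null(landmarks)) {
    sim <- sample_landmarks(config)
    landmarks <- sim$configurations
    if (is.null(expression)) expression <- sim$truth$expression
  }
  if (is.null(expression))
    stopf("stage `input`: supplied landmarks need matching `expression` values")
  if (length(expression) != length(landmarks))
    stopf("stage `input`: one expression value per specimen required")

  aligned <- tryCatch(generalized_procrustes(landmarks),
                      error = function(e) stopf("stage `gpa`: %s",
                                                conditionMessage(e)))
  md <- aligned$metadata
  wt <- unique(md$genotype[vapply(config$genotypes, function(g)
    g$is_wild_type, TRUE)[match(md$genotype,
                                vapply(config$genotypes,
                                       function(g) g$name, ""))]])
  wt <- wt[!is.na(wt)][1]
  if (is.na(wt)) stopf("stage `lab_offset`: no wild-type genotype in config")

  if (length(unique(md$lab)) > 1)
    aligned <- tryCatch(remove_lab_offset(aligned, wt),
                        error = function(e) stopf("stage `lab_offset`: %s",
                                                  conditionMessage(e)))
  if (!is.null(standardize_on))
    aligned <- tryCatch(standardize_shapes(aligned, standardize_on),
                        error = function(e) stopf("stage `standardize`: %s",
                                                  conditionMessage(e)))

  reg <- shape_regression(aligned, expression)
  scores <- reg$regression_scores

  fit_x <- expression; fit_z <- scores
  if (curve_fit == "genotype_mean") {
    fit_x <- tapply(expression, md$genotype, mean)
    fit_z <- tapply(scores, md$genotype, mean)
    fit_x <- as.numeric(fit_x); fit_z <- as.numeric(fit_z)
  }
  fit <- fit_vb(fit_x, fit_z)
  if (is.null(fit$params)) stopf("stage `curve_fit`: fit failed to converge")

  pooled_sd <- sqrt(mean(tapply(expression, md$genotype, stats::var),
                         na.rm = TRUE))
  disp <- procrustes_variance(aligned, md$genotype)
  gt_names <- vapply(config$genotypes, function(g) g$name, "")
  per <- do.call(rbind, lapply(config$genotypes, function(g) {
    idx <- md$genotype == g$name
    spec <- truncnorm_spec(mean(expression[idx]), pooled_sd)
    data.frame(
      genotype = g$name,
      n = sum(idx),
      mean_expression = mean(expression[idx]),
      sd_expression = stats::sd(expression[idx]),
      mean_score = mean(scores[idx]),
      observed_disparity = disp$disparity[match(g$name, disp$group)],
      predicted_var_first_order = predicted_variance(fit$params, spec,
                                                     "first_order"),
      predicted_var_exact = predicted_variance(fit$params, spec, "exact"),
      stringsAsFactors = FALSE)
  }))

  ok <- is.finite(per$observed_disparity)
  rho <- stats::cor(per$predicted_var_exact[ok], per$observed_disparity[ok],
                    method = "spearman")
  tests <- list(levene = levene_test(expression, md$genotype),
                anova = oneway_anova(expression, md$genotype))
  disp_p <- NULL
  if (n_perm > 0)
    disp_p <- disparity_permutation_test(aligned, md$genotype,
                                         n_perm = n_perm, seed = seed)

  report <- structure(list(
    per_genotype = per, fit = fit,
    regression = list(r_squared = reg$r_squared),
    threshold = threshold_expression(fit$params, slope_fraction),
    spearman_predicted_observed = rho,
    expression_tests = tests, disparity_p = disp_p,
    aligned = aligned, scores = scores, expression = expression,
    wild_type = wt, seed = seed), class = "robustness_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    shp <- data.frame(specimen_id = md$specimen_id, genotype = md$genotype,
                      aligned$shapes, check.names = FALSE)
    utils::write.csv(shp, file.path(out_dir, "aligned_shapes.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(specimen_id = md$specimen_id,
                                genotype = md$genotype,
                                expression = expression, score = scores),
                     file.path(out_dir, "regression_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(per, file.path(out_dir, "robustness_report.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(L_m = fit$params$L_m, L_0 = fit$params$L_0,
                          k = fit$params$k, r_squared = fit$r_squared,
                          converged = fit$converged,
                          threshold = report$threshold,
                          spearman = rho, seed = seed),
                     file.path(out_dir, "curve_fit.yaml"))
    if (!is.null(disp_p))
      utils::write.csv(as.data.frame(disp_p),
                       file.path(out_dir, "disparity_p_values.csv"))
  }
  report
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Allelic-series robustness report\n")
  cat(sprintf("  curve: L_m = %.4g, L_0 = %.4g, k = %.4g (R^2 = %.3f)\n",
              x$fit$params$L_m, x$fit$params$L_0, x$fit$params$k,
              x$fit$r_squared))
  cat(sprintf("  shape ~ expression R^2 = %.3f\n", x$regression$r_squared))
  cat(sprintf("  threshold expression (10%% slope) = %.3f\n", x$threshold))
  cat(sprintf("  Spearman(predicted, observed variance) = %.3f\n",
              x$spearman_predicted_observed))
  cat(sprintf("  Levene P = %.4g, ANOVA P = %.4g\n",
              x$expression_tests$levene$p.value,
              x$expression_tests$anova$p.value))
  print(x$per_genotype[, c("genotype", "n", "mean_expression",
                           "observed_disparity", "predicted_var_exact")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
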