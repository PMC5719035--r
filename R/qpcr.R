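# qPCR relative quantification and the routine dispersion/location tests
# applied to expression values across genotypes.

#' Delta-delta-Ct relative expression
#'
#' Per sample, `dCt = mean Ct(target) - mean Ct(reference)`; the
#' wild-type group mean of `dCt` is computed first and subtracted
#' (`ddCt`), and relative expression is `2^(-ddCt)`. Because the group
#' mean is taken on the Ct scale before exponentiation, the wild-type
#' group mean of the returned values is close to, but not exactly, 1.
#'
#' @param ct Data.frame with columns `sample_id`, `genotype`, `gene`,
#'   `replicate`, `ct`.
#' @param target,reference Gene labels.
#' @param wt_genotype Wild-type genotype label.
#' @return Data.frame: `sample_id`, `genotype`, `delta_ct`,
#'   `delta_delta_ct`, `relative_expression`.
#' @export
delta_delta_ct <- function(ct, target = "Fgf8", reference = "Gapdh",
                           wt_genotype = "WT") {
  need <- c("sample_id", "genotype", "gene", "ct")
  if (!all(need %in% names(ct))) stopf("`ct` must have columns %s",
                                       paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stopf("Ct values must be finite and positive")
  samples <- unique(ct$sample_id)
  rows <- lapply(samples, function(s) {
    sub <- ct[ct$sample_id == s, ]
    tgt <- sub$ct[sub$gene == target]
    ref <- sub$ct[sub$gene == reference]
    if (length(ref) == 0) stopf("sample %s lacks reference gene `%s`", s, reference)
    if (length(tgt) == 0) stopf("sample %s lacks target gene `%s`", s, target)
    data.frame(sample_id = s, genotype = sub$genotype[1],
               delta_ct = mean(tgt) - mean(ref), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  wt <- out$genotype == wt_genotype
  if (!any(wt)) stopf("no samples with wild-type genotype `%s`", wt_genotype)
  out$delta_delta_ct <- out$delta_ct - mean(out$delta_ct[wt])
  out$relative_expression <- 2^(-out$delta_delta_ct)
  out
}

#' Levene's test for homogeneity of variance
#'
#' Classical Levene W on absolute deviations from the group means
#' (mean-centered variant), with an F reference distribution. Used to
#' test whether expression variance is homogeneous across the allelic
#' series.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 groups, each n >= 2).
#' @return List with `statistic` (W), `df` (within, between), `p.value`.
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("each group needs n >= 2")
  lt <- car::leveneTest(values, groups, center = mean)
  list(statistic = lt[["F value"]][1],
       df = c(within = lt$Df[2], between = lt$Df[1]),
       p.value = lt[["Pr(>F)"]][1])
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way decomposition (equal-variance F test);
#' degrees of freedom are reported as (within, between) to mirror the
#' reporting convention used for the allelic series.
#'
#' @inheritParams levene_test
#' @return List with `statistic` (F), `df` (within, between), `p.value`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  fit <- stats::anova(stats::lm(values ~ groups))
  list(statistic = fit[["F value"]][1],
       df = c(within = fit$Df[2], between = fit$Df[1]),
       p.value = fit[["Pr(>F)"]][1])
}
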