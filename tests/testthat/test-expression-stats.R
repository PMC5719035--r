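# qPCR quantification, dispersion/location tests, normalization, and the
# transcriptome resampling statistics.

make_ct <- function(samples, genotypes, dct) {
  do.call(rbind, Map(function(s, g, d)
    data.frame(sample_id = s, genotype = g,
               gene = c("Gapdh", "Fgf8"), replicate = 1L,
               ct = c(20, 20 + d), stringsAsFactors = FALSE),
    samples, genotypes, dct))
}

test_that("delta-delta-Ct arithmetic and its invariances hold", {
  # single WT sample: exactly 1
  ct <- make_ct(c("s1", "s2"), c("WT", "mut"), c(5, 7))
  dd <- delta_delta_ct(ct, wt_genotype = "WT")
  expect_equal(dd$relative_expression[dd$sample_id == "s1"], 1.0)
  # two cycles above the WT mean: 2^-2 = 0.25
  expect_equal(dd$relative_expression[dd$sample_id == "s2"], 0.25)
  # invariance under adding a constant to all Ct values of one sample
  ct2 <- ct
  ct2$ct[ct2$sample_id == "s2"] <- ct2$ct[ct2$sample_id == "s2"] + 3.7
  expect_equal(delta_delta_ct(ct2, wt_genotype = "WT")$relative_expression,
               dd$relative_expression)
  # missing reference is an error naming the sample
  expect_error(delta_delta_ct(ct[ct$gene == "Fgf8" | ct$sample_id == "s1", ],
                              wt_genotype = "WT"), "s2")
})

test_that("a noisy WT group has mean relative expression slightly above 1", {
  set.seed(1)
  n <- 400
  ct <- make_ct(sprintf("w%d", 1:n), rep("WT", n), rnorm(n, 5, 0.5))
  dd <- delta_delta_ct(ct, wt_genotype = "WT")
  # Jensen: E[2^-x] > 2^-E[x] = 1 when x varies
  expect_gt(mean(dd$relative_expression), 1)
})

test_that("Levene's test matches its textbook formula on a 3-group toy", {
  vals <- c(1, 2, 3, 6, 8, 10, 2, 2.5, 3.5, 4)
  grp <- c("a", "a", "a", "b", "b", "b", "c", "c", "c", "c")
  lt <- levene_test(vals, grp)
  # direct evaluation: one-way ANOVA F on |x - group mean|
  z <- abs(vals - ave(vals, grp))
  or <- stats::anova(stats::lm(z ~ grp))
  expect_equal(lt$statistic, or[["F value"]][1], tolerance = 1e-10)
  expect_equal(lt$p.value, or[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(unname(lt$df), c(7, 2))
  # identical spreads: W = 0, P = 1
  lt0 <- levene_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(lt0$statistic, 0)
  expect_equal(lt0$p.value, 1)
})

test_that("one-way ANOVA equals the squared t test for two groups", {
  set.seed(2)
  x <- c(rnorm(8), rnorm(8, 1))
  g <- rep(c("a", "b"), each = 8)
  an <- oneway_anova(x, g)
  tt <- stats::t.test(x ~ g, var.equal = TRUE)
  expect_equal(an$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p.value, tt$p.value, tolerance = 1e-10)
  # identical group means: F ~ 0
  an0 <- oneway_anova(rep(c(1, 2), 6), rep(c("a", "b"), each = 6))
  expect_lt(an0$statistic, 1e-10)
})

test_that("expression across the default series: strong means signal, homogeneous variance", {
  sim <- sample_landmarks(series_config(seed = 91))
  eps <- sim$truth$expression
  g <- sim$truth$genotype
  expect_lt(oneway_anova(eps, g)$p.value, 1e-3)
  expect_gt(levene_test(eps, g)$p.value, 0.05)
})

test_that("median-of-ratios size factors behave and match DESeq2", {
  set.seed(3)
  base <- rpois(200, 300) + 1
  counts <- cbind(s1 = base, s2 = base, s3 = base)
  sf <- size_factor_normalize(counts)
  expect_equal(unname(sf$size_factors), rep(1, 3))
  # doubling one sample doubles its factor relative to the others (size
  # factors are anchored to the per-gene geometric mean, so the absolute
  # factors shift by the common constant 2^(1/n))
  counts2 <- counts; counts2[, 2] <- counts2[, 2] * 2
  sf2 <- size_factor_normalize(counts2)
  expect_equal(unname(sf2$size_factors[2] / sf2$size_factors[1]), 2,
               tolerance = 1e-10)
  expect_equal(sf2$normalized / sf2$normalized[1, 1],
               sf$normalized / sf$normalized[1, 1], tolerance = 1e-10)
  # independent implementation agreement on an NB matrix
  cfg <- small_series(seed = 101, noise_sd = 0.01)
  cm <- sample_counts(cfg, default_gene_models(seed = 11), seed = 12,
                      n_per_genotype = 4)
  ours <- size_factor_normalize(cm$counts)$size_factors
  theirs <- DESeq2::estimateSizeFactorsForMatrix(cm$counts)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
  # size factors recover the true library factors (up to a common scale)
  ratio <- ours / cm$metadata$library_factor
  rel_err <- abs(ratio / stats::median(ratio) - 1)
  expect_lt(stats::median(rel_err), 0.05)
  expect_error(size_factor_normalize(matrix(c(0, 1, 1, 0), 2)), "nonzero")
})

test_that("fold-change profiles reflect constructed changes", {
  set.seed(4)
  n_gene <- 40
  wt_mean <- rep(200, n_gene)
  norm <- cbind(matrix(rpois(n_gene * 6, wt_mean), n_gene),
                matrix(rpois(n_gene * 6, wt_mean), n_gene))
  # genotype "mut": first half of the set doubled
  norm[1:20, 7:12] <- matrix(rpois(20 * 6, 400), 20)
  rownames(norm) <- sprintf("g%02d", 1:n_gene)
  colnames(norm) <- c(sprintf("wt%d", 1:6), sprintf("mut%d", 1:6))
  set <- gene_set("all", rownames(norm))
  prof <- foldchange_profile(norm, rep(c("WT", "mut"), each = 6), "WT", set)
  # half the genes at |log2 FC| = 1, half near 0 -> mean about 0.5
  expect_lt(abs(prof$mean_abs_log2fc - 0.5), 0.1)
  # a genotype drawn identically to WT sits near the 1-fold baseline
  norm0 <- matrix(rpois(n_gene * 12, 200), n_gene,
                  dimnames = list(rownames(norm), NULL))
  prof0 <- foldchange_profile(norm0, rep(c("WT", "same"), each = 6), "WT", set)
  expect_lt(prof0$mean_abs_log2fc, 0.15)
  # missing set members are reported, not dropped silently
  expect_warning(
    foldchange_profile(norm, rep(c("WT", "mut"), each = 6), "WT",
                       gene_set("odd", c("g01", "absent_gene"))),
    "absent_gene")
})

test_that("neighbor bootstrap flags a step change and is reproducible", {
  set.seed(5)
  n_gene <- 30
  mk <- function(mu, n) matrix(rpois(n_gene * n, mu), n_gene)
  norm <- cbind(mk(200, 4), mk(200, 4), mk(600, 4))   # 3x step at group c
  rownames(norm) <- sprintf("g%02d", 1:n_gene)
  genotypes <- rep(c("WT", "b", "c"), each = 4)
  set <- gene_set("s", rownames(norm))
  r1 <- neighbor_bootstrap_test(norm, genotypes, c("WT", "b", "c"), "WT",
                                set, n_boot = 999, seed = 6)
  expect_identical(r1,
    neighbor_bootstrap_test(norm, genotypes, c("WT", "b", "c"), "WT",
                            set, n_boot = 999, seed = 6))
  expect_gt(r1$p.value[r1$genotype_a == "WT"], 0.05)   # WT vs identical b
  expect_lt(r1$p.value[r1$genotype_a == "b"], 0.05)    # b vs 3x-changed c
  # undersized groups are flagged with NA P
  keep <- c(1:8, 9)                      # group "c" reduced to one sample
  r2 <- neighbor_bootstrap_test(norm[, keep], genotypes[keep],
                                c("WT", "b", "c"), "WT", set,
                                n_boot = 999, seed = 6)
  expect_true(r2$flagged[r2$genotype_b == "c"])
  expect_true(is.na(r2$p.value[r2$genotype_b == "c"]))
})

test_that("within-genotype concordance detects dysregulation and caps z", {
  set.seed(7)
  n_gene <- 50
  profile <- runif(n_gene, 3, 9)          # log2-scale base profile
  mk_ind <- function(noise) 2^(profile + rnorm(n_gene, 0, noise)) - 1
  norm <- cbind(
    vapply(1:5, function(i) mk_ind(0.3), numeric(n_gene)),   # WT
    vapply(1:5, function(i) mk_ind(0.3), numeric(n_gene)),   # same law
    vapply(1:5, function(i) mk_ind(1.2), numeric(n_gene)))   # dysregulated
  rownames(norm) <- sprintf("g%02d", 1:n_gene)
  genotypes <- rep(c("WT", "same", "noisy"), each = 5)
  set <- gene_set("s", rownames(norm))
  cc <- within_genotype_concordance(norm, genotypes, "WT", set,
                                    n_boot = 999, seed = 8)
  z_wt <- cc$mean_z[cc$genotype == "WT"]
  expect_gt(cc$p_vs_wt[cc$genotype == "same"], 0.05)
  expect_lt(cc$p_vs_wt[cc$genotype == "noisy"], 0.05)
  expect_lt(cc$mean_z[cc$genotype == "noisy"], z_wt)
  # identical individuals: correlation 1 is capped, not infinite
  dup <- cbind(norm[, 1], norm[, 1], norm[, 6], norm[, 7])
  cc2 <- within_genotype_concordance(dup, c("d", "d", "WT", "WT"), "WT",
                                     set, n_boot = 999, seed = 9)
  expect_true(is.finite(cc2$mean_z[cc2$genotype == "d"]))
  expect_lte(cc2$mean_z[cc2$genotype == "d"], atanh(1 - 1e-12))
})

test_that("gene-set correlation tests recover configured response classes", {
  cfg <- series_config(seed = 111)
  genes <- default_gene_models(n_unresponsive = 200, n_nonlinear = 25,
                               n_linear = 0, n_compensatory = 8,
                               dispersion = 0.02, seed = 13)
  cm <- sample_counts(cfg, genes, seed = 14, n_per_genotype = 3)
  norm <- size_factor_normalize(cm$counts)$normalized
  cls <- vapply(cm$genes, function(g) g$response_class, "")
  ids <- vapply(cm$genes, function(g) g$gene_id, "")
  sets <- list(gene_set("downstream", ids[cls == "downstream_nonlinear"]),
               gene_set("compensatory", ids[cls == "compensatory_negative"]))
  res <- geneset_fgf8_correlation_test(norm, cm$metadata$expression, sets,
                                       n_resample = 999, seed = 15)
  expect_equal(res$sets$flag[res$sets$name == "downstream"], "high")
  expect_equal(res$sets$flag[res$sets$name == "compensatory"], "low")
  expect_error(
    geneset_fgf8_correlation_test(norm, cm$metadata$expression, sets,
                                  n_resample = 0), "999")
})

test_that("transcriptome PC1 tracks expression when downstream genes respond", {
  cfg <- series_config(seed = 121)
  genes <- default_gene_models(n_unresponsive = 150, n_nonlinear = 60,
                               n_linear = 30, n_compensatory = 5,
                               dispersion = 0.02, seed = 16)
  cm <- sample_counts(cfg, genes, seed = 17, n_per_genotype = 2)
  norm <- size_factor_normalize(cm$counts)$normalized
  pc <- shape_pca(t(log2(norm + 1)))
  expect_gt(abs(stats::cor(pc$scores[, 1], cm$metadata$expression)), 0.8)
})
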