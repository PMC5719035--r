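# Transcriptome-level statistics: median-of-ratios normalization,
# fold-change profiles across the series, nearest-neighbor bootstrap
# tests, within-genotype concordance of expression, and gene-set
# correlation tests against the perturbed gene's level with genome-wide
# resampling.

#' A named gene set
#'
#' @param name Set label.
#' @param members Character vector of gene ids.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  structure(list(name = as.character(name),
                 members = unique(as.character(members))),
            class = "gene_set")
}

# Members present in the matrix; missing ones reported via warning,
# never silently dropped.
.set_members <- function(set, norm) {
  stopifnot(inherits(set, "gene_set"))
  present <- set$members %in% rownames(norm)
  if (!all(present))
    warning(sprintf("gene set `%s`: %d member(s) absent from the matrix: %s",
                    set$name, sum(!present),
                    paste(utils::head(set$members[!present], 5), collapse = ", ")))
  set$members[present]
}

#' Median-of-ratios size-factor normalization
#'
#' For each gene with nonzero counts in every sample, the ratio of each
#' sample's count to the gene's geometric mean is formed; a sample's size
#' factor is the median of those ratios, and normalized counts are the
#' raw counts divided by it. The geometric mean of the size factors is
#' close to 1 by construction.
#'
#' @param counts Genes x samples matrix of nonnegative counts (>= 2
#'   samples).
#' @return List with `normalized` (same dimensions) and `size_factors`.
#' @export
size_factor_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stopf("need at least 2 samples")
  if (any(counts < 0)) stopf("counts must be nonnegative")
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero))
    stopf(paste("no gene has nonzero counts in every sample;",
                "filter to higher-expressed genes or pool samples"))
  log_geo <- rowMeans(log(counts[all_nonzero, , drop = FALSE]))
  sf <- apply(counts[all_nonzero, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - log_geo)))
  list(normalized = sweep(counts, 2, sf, `/`), size_factors = sf)
}

# Per-gene log2 fold change of a genotype vs the wild-type group, with a
# delta-method standard error, on normalized counts.
.log2fc_table <- function(norm, cols_g, cols_wt) {
  m_g <- rowMeans(norm[, cols_g, drop = FALSE])
  m_wt <- rowMeans(norm[, cols_wt, drop = FALSE])
  v_g <- apply(norm[, cols_g, drop = FALSE], 1, stats::var)
  v_wt <- apply(norm[, cols_wt, drop = FALSE], 1, stats::var)
  ok <- m_wt > 0 & m_g > 0
  l2 <- log(2)
  data.frame(
    log2fc = ifelse(ok, log2(m_g / m_wt), NA_real_),
    se = ifelse(ok, sqrt(v_g / (length(cols_g) * m_g^2) +
                           v_wt / (length(cols_wt) * m_wt^2)) / l2, NA_real_))
}

#' Fold-change profile of a gene set across the allelic series
#'
#' For every genotype, the average absolute log2 fold change of the
#' set's genes relative to the wild-type group, together with the average
#' absolute standard error of the fold change (per-gene delta-method SEs,
#' averaged over the set). Genes with a zero mean in either group are
#' excluded and reported in the `excluded_genes` attribute.
#'
#' @param norm Normalized genes x samples matrix.
#' @param genotypes Genotype label per sample (length = ncol(norm)).
#' @param wt Wild-type genotype label.
#' @param set A [gene_set()].
#' @return Data.frame: `genotype`, `n_samples`, `mean_abs_log2fc`,
#'   `mean_abs_se`, `n_genes`.
#' @export
foldchange_profile <- function(norm, genotypes, wt, set) {
  genotypes <- as.character(genotypes)
  if (length(genotypes) != ncol(norm)) stopf("one genotype per sample required")
  if (!wt %in% genotypes) stopf("wild-type group `%s` absent", wt)
  members <- .set_members(set, norm)
  if (length(members) == 0) stopf("gene set `%s` is empty in this matrix", set$name)
  sub <- norm[members, , drop = FALSE]
  cols_wt <- which(genotypes == wt)
  lv <- setdiff(unique(genotypes), wt)
  excluded <- character()
  rows <- lapply(lv, function(g) {
    tab <- .log2fc_table(sub, which(genotypes == g), cols_wt)
    drop <- is.na(tab$log2fc)
    excluded <<- union(excluded, members[drop])
    data.frame(genotype = g, n_samples = sum(genotypes == g),
               mean_abs_log2fc = mean(abs(tab$log2fc[!drop])),
               mean_abs_se = mean(abs(tab$se[!drop])),
               n_genes = sum(!drop), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded_genes") <- excluded
  out
}

#' Nearest-neighbor resampling test on fold-change profiles
#'
#' For each adjacent pair in `genotype_order` (ordered by mean
#' expression), the statistic is the absolute difference of the two
#' groups' mean absolute log2 fold changes versus wild type (the
#' wild-type group's own fold change is identically zero). The null
#' resamples samples within the pooled pair, group sizes preserved, with
#' the add-one P convention. Two resampling schemes are available:
#' `"permutation"` (default) reassigns the pooled samples without
#' replacement, which is exchangeable under the null and therefore
#' calibrated even at very small group sizes; `"bootstrap"` draws both
#' pseudo-groups with replacement from the pool, which is conservative
#' at small n because pseudo-group means are overdispersed relative to
#' the observed ones. When a pair includes the wild type, the reference
#' mean is recomputed from the pseudo-wild-type samples in each
#' resample, so the null statistic has the same structure as the
#' observed one.
#'
#' @inheritParams foldchange_profile
#' @param genotype_order Genotype labels ordered along the series.
#' @param n_boot Resampling replicates (>= 999).
#' @param seed Integer seed.
#' @param method `"permutation"` or `"bootstrap"`.
#' @return Data.frame per adjacent pair: `genotype_a`, `genotype_b`,
#'   `statistic`, `p.value`, `flagged` (TRUE when a group has < 2
#'   samples, in which case P is NA).
#' @export
neighbor_bootstrap_test <- function(norm, genotypes, genotype_order, wt, set,
                                    n_boot = 999, seed = NULL,
                                    method = c("permutation", "bootstrap")) {
  method <- match.arg(method)
  if (n_boot < 999) stopf("`n_boot` must be at least 999")
  genotypes <- as.character(genotypes)
  members <- .set_members(set, norm)
  sub <- norm[members, , drop = FALSE]
  cols_wt <- which(genotypes == wt)
  m_wt_fixed <- rowMeans(sub[, cols_wt, drop = FALSE])
  mean_abs_fc <- function(cols, ref) {
    m_g <- rowMeans(sub[, cols, drop = FALSE])
    use <- ref > 0 & m_g > 0
    mean(abs(log2(m_g[use] / ref[use])))
  }
  # statistic for a pair: when one side is the wild type its fold change
  # is 0 and the other side is measured against that side's samples
  pair_stat <- function(ca, cb, a_is_wt, b_is_wt) {
    if (a_is_wt) {
      mean_abs_fc(cb, rowMeans(sub[, ca, drop = FALSE]))
    } else if (b_is_wt) {
      mean_abs_fc(ca, rowMeans(sub[, cb, drop = FALSE]))
    } else {
      abs(mean_abs_fc(ca, m_wt_fixed) - mean_abs_fc(cb, m_wt_fixed))
    }
  }
  pairs <- cbind(genotype_order[-length(genotype_order)], genotype_order[-1])
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(pairs)), function(r) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      ca <- which(genotypes == a); cb <- which(genotypes == b)
      a_wt <- a == wt; b_wt <- b == wt
      obs <- pair_stat(ca, cb, a_wt, b_wt)
      if (length(ca) < 2 || length(cb) < 2)
        return(data.frame(genotype_a = a, genotype_b = b, statistic = obs,
                          p.value = NA_real_, flagged = TRUE))
      pool <- c(ca, cb)
      na <- length(ca)
      null <- vapply(seq_len(n_boot), function(i) {
        if (method == "permutation") {
          s <- sample(pool)
          ra <- s[seq_len(na)]; rb <- s[-seq_len(na)]
        } else {
          ra <- sample(pool, na, replace = TRUE)
          rb <- sample(pool, length(cb), replace = TRUE)
        }
        pair_stat(ra, rb, a_wt, b_wt)
      }, 1.0)
      data.frame(genotype_a = a, genotype_b = b, statistic = obs,
                 p.value = (1 + sum(null >= obs - 1e-15)) / (n_boot + 1),
                 flagged = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Within-genotype concordance of expression profiles
#'
#' For each genotype, Pearson correlations between every pair of
#' individuals across the set's genes (on `log2(normalized + 1)`),
#' Fisher z-transformed (capped at `atanh(1 - 1e-12)` for perfect
#' correlations). Each genotype's mean z is compared with the wild-type
#' group by a two-sided percentile bootstrap over individuals (each group
#' resampled with replacement within itself; P is twice the smaller tail
#' proportion of the bootstrap difference around zero, add-one,
#' capped at 1). Pairs involving an individual with a constant profile
#' are skipped and counted in `n_skipped`.
#'
#' @inheritParams foldchange_profile
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return Data.frame per genotype: `genotype`, `n_pairs`, `mean_z`,
#'   `p_vs_wt` (NA for the wild type itself), `n_skipped`.
#' @export
within_genotype_concordance <- function(norm, genotypes, wt, set,
                                        n_boot = 999, seed = NULL) {
  genotypes <- as.character(genotypes)
  members <- .set_members(set, norm)
  if (length(members) < 3) stopf("gene set must have at least 3 genes present")
  lx <- log2(norm[members, , drop = FALSE] + 1)
  zcap <- atanh(1 - 1e-12)
  # `cols` may contain duplicated individuals under bootstrap resampling;
  # self-pairs (identical individuals, r = 1 artifacts) are excluded
  pair_z <- function(cols) {
    if (length(cols) < 2) return(list(z = numeric(), skipped = 0L))
    cm <- lx[, cols, drop = FALSE]
    sds <- apply(cm, 2, stats::sd)
    usable <- which(sds > 0)
    z <- c()
    if (length(usable) >= 2) {
      rc <- stats::cor(cm[, usable, drop = FALSE])
      distinct <- outer(cols[usable], cols[usable], `!=`)
      keep <- upper.tri(rc) & distinct
      z <- atanh(pmin(pmax(rc[keep], -1 + 1e-15), 1 - 1e-12))
      z <- pmin(pmax(z, -zcap), zcap)
    }
    skipped <- choose(length(cols), 2) - choose(length(usable), 2)
    list(z = z, skipped = as.integer(skipped))
  }
  mean_z_of <- function(cols) mean(pair_z(cols)$z)
  lv <- unique(genotypes)
  cols_wt <- which(genotypes == wt)
  with_seed(seed, {
    rows <- lapply(lv, function(g) {
      cols <- which(genotypes == g)
      pz <- pair_z(cols)
      p <- NA_real_
      if (g != wt && length(cols) >= 2 && length(cols_wt) >= 2) {
        diffs <- vapply(seq_len(n_boot), function(i) {
          ra <- sample(cols, length(cols), replace = TRUE)
          rb <- sample(cols_wt, length(cols_wt), replace = TRUE)
          mean_z_of(ra) - mean_z_of(rb)
        }, 1.0)
        diffs <- diffs[is.finite(diffs)]
        lo <- (1 + sum(diffs <= 0)) / (length(diffs) + 1)
        hi <- (1 + sum(diffs >= 0)) / (length(diffs) + 1)
        p <- min(1, 2 * min(lo, hi))
      }
      data.frame(genotype = g, n_pairs = length(pz$z), mean_z = mean(pz$z),
                 p_vs_wt = p, n_skipped = pz$skipped,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Gene-set correlation with the perturbed gene's level, by resampling
#'
#' Per gene, the Pearson correlation of `log2(normalized + 1)` expression
#' with the measured expression level of the perturbed gene across
#' samples. Each set's statistic is the mean correlation of its members;
#' the null is the same statistic on `n_resample` random gene sets of the
#' same size drawn genome-wide, giving a 95% interval and a two-sided
#' resampling P. Member genes are additionally flagged when they fall
#' outside the central 95% of the genome-wide single-gene correlation
#' distribution.
#'
#' @param norm Normalized genes x samples matrix.
#' @param fgf8_levels Measured perturbed-gene level per sample.
#' @param sets A [gene_set()] or list of them.
#' @param n_resample Number of random sets (>= 999).
#' @param seed Integer seed.
#' @return List with `sets` (data.frame: name, n_genes, observed, ci_lo,
#'   ci_hi, flag in {"high","low","none"}, p.value) and `genes`
#'   (data.frame per member gene: set, gene_id, correlation, flag).
#' @export
geneset_fgf8_correlation_test <- function(norm, fgf8_levels, sets,
                                          n_resample = 999, seed = NULL) {
  if (n_resample < 999) stopf("`n_resample` must be at least 999")
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (length(fgf8_levels) != ncol(norm))
    stopf("one expression level per sample required")
  lx <- log2(as.matrix(norm) + 1)
  sds <- apply(lx, 1, stats::sd)
  usable <- sds > 0
  r_all <- rep(NA_real_, nrow(lx))
  r_all[usable] <- as.vector(stats::cor(t(lx[usable, , drop = FALSE]),
                                        fgf8_levels))
  names(r_all) <- rownames(lx)
  gene_band <- stats::quantile(r_all, c(0.025, 0.975), na.rm = TRUE)
  pool <- which(!is.na(r_all))
  with_seed(seed, {
    set_rows <- list(); gene_rows <- list()
    for (s in sets) {
      members <- .set_members(s, norm)
      rs <- r_all[members]
      obs <- mean(rs, na.rm = TRUE)
      m <- sum(!is.na(rs))
      null <- vapply(seq_len(n_resample), function(i)
        mean(r_all[sample(pool, m)]), 1.0)
      ci <- stats::quantile(null, c(0.025, 0.975), names = FALSE)
      flag <- if (obs > ci[2]) "high" else if (obs < ci[1]) "low" else "none"
      p <- 2 * min((1 + sum(null >= obs)) / (n_resample + 1),
                   (1 + sum(null <= obs)) / (n_resample + 1))
      set_rows[[s$name]] <- data.frame(
        name = s$name, n_genes = m, observed = obs,
        ci_lo = ci[1], ci_hi = ci[2], flag = flag, p.value = min(p, 1),
        stringsAsFactors = FALSE)
      gene_rows[[s$name]] <- data.frame(
        set = s$name, gene_id = members, correlation = unname(rs),
        flag = ifelse(is.na(rs), "none",
                      ifelse(rs > gene_band[2], "high",
                             ifelse(rs < gene_band[1], "low", "none"))),
        stringsAsFactors = FALSE)
    }
    list(sets = do.call(rbind, c(set_rows, list(make.row.names = FALSE))),
         genes = do.call(rbind, c(gene_rows, list(make.row.names = FALSE))))
  })
}
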