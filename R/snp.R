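# SNP-frequency summaries: allele frequencies per group, additive
# genetic variance (2pq with unit allelic effects), and a relative
# inbreeding coefficient. Used to show genomic variance does not track
# phenotypic variance across an allelic series.

.check_snp_matrix <- function(m) {
  m <- as.matrix(m)
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stopf("genotypes must be coded 0/1/2 (alt-allele dosage) or NA")
  m
}

#' Per-locus allele frequencies within a group
#'
#' Alt-allele frequency `p = mean(dosage)/2` over non-missing genotypes
#' of the group's samples; loci with no calls in the group get `NA` and
#' are flagged.
#'
#' @param m Loci x samples matrix of 0/1/2 dosages (NA = missing).
#' @param group Per-sample labels; frequencies are computed within each
#'   label.
#' @return Data.frame: `locus`, one frequency column per group, plus
#'   `missing_<group>` columns with the fraction of missing calls.
#' @export
allele_frequencies <- function(m, group) {
  m <- .check_snp_matrix(m)
  group <- as.character(group)
  if (length(group) != ncol(m)) stopf("one group label per sample required")
  lv <- unique(group)
  out <- data.frame(locus = rownames(m) %||% seq_len(nrow(m)),
                    stringsAsFactors = FALSE)
  for (g in lv) {
    sub <- m[, group == g, drop = FALSE]
    n_ok <- rowSums(!is.na(sub))
    out[[paste0("freq_", g)]] <- ifelse(n_ok > 0,
                                        rowMeans(sub, na.rm = TRUE) / 2,
                                        NA_real_)
    out[[paste0("missing_", g)]] <- 1 - n_ok / ncol(sub)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Additive genetic variance from allele frequencies
#'
#' `2 p (1 - p)` per locus under unit allelic effects, summed over loci
#' with defined frequencies. Reported variance is therefore relative (the
#' study compares groups, not absolute genetic variances).
#'
#' @param freqs Numeric vector of per-locus allele frequencies in [0, 1]
#'   (NA allowed; such loci are skipped).
#' @return List with `total` and `per_locus`.
#' @export
additive_variance <- function(freqs) {
  ok <- !is.na(freqs)
  if (any(freqs[ok] < 0 | freqs[ok] > 1))
    stopf("frequencies must lie in [0, 1]")
  per <- ifelse(ok, 2 * freqs * (1 - freqs), NA_real_)
  list(total = sum(per, na.rm = TRUE), per_locus = per)
}

#' Relative inbreeding coefficient of a group
#'
#' `F = 1 - mean(H_obs / H_exp)` over loci polymorphic within the group,
#' with `H_obs` the observed heterozygote fraction and
#' `H_exp = 2 p (1 - p)`.
#'
#' @inheritParams allele_frequencies
#' @return Data.frame: `group`, `F`, `n_polymorphic`, `defined`.
#' @export
inbreeding_coefficient <- function(m, group) {
  m <- .check_snp_matrix(m)
  group <- as.character(group)
  if (length(group) != ncol(m)) stopf("one group label per sample required")
  lv <- unique(group)
  rows <- lapply(lv, function(g) {
    sub <- m[, group == g, drop = FALSE]
    p <- rowMeans(sub, na.rm = TRUE) / 2
    h_exp <- 2 * p * (1 - p)
    poly <- which(!is.na(p) & h_exp > 0)
    if (length(poly) == 0)
      return(data.frame(group = g, F = NA_real_, n_polymorphic = 0L,
                        defined = FALSE, stringsAsFactors = FALSE))
    h_obs <- rowMeans(sub[poly, , drop = FALSE] == 1, na.rm = TRUE)
    data.frame(group = g, F = 1 - mean(h_obs / h_exp[poly]),
               n_polymorphic = length(poly), defined = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
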