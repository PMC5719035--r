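# Synthetic molecular readouts for the allelic series: negative-binomial
# RNA-seq counts with known response classes, triplicate qPCR Ct tables,
# and near-isogenic SNP panels.

#' Gene response model for synthetic count data
#'
#' Describes how one gene's expected count responds to the developmental
#' signal `eps` (relative expression of the perturbed gene). Response
#' classes: `downstream_nonlinear` (saturating response mirroring the G-P
#' curve), `downstream_linear`, `compensatory_negative` (expression rises
#' as `eps` falls), and `unresponsive` (constant multiplier 1). The
#' multiplier equals 1 at `eps = 1`, so wild-type samples sit at the
#' baseline mean.
#'
#' @param gene_id Gene label.
#' @param response_class One of the four classes above.
#' @param baseline_mean Expected count at wild-type expression (> 0).
#' @param response_curve Named list of class-specific parameters:
#'   `A`, `k` (nonlinear), `c` (linear), `gamma` (compensatory).
#' @param dispersion Negative-binomial dispersion (> 0; variance =
#'   mu + dispersion * mu^2). Values below 1e-8 are treated as Poisson.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id,
                       response_class = c("unresponsive",
                                          "downstream_nonlinear",
                                          "downstream_linear",
                                          "compensatory_negative"),
                       baseline_mean = 100,
                       response_curve = list(),
                       dispersion = 0.05) {
  response_class <- match.arg(response_class)
  if (!is_scalar_number(baseline_mean) || baseline_mean <= 0)
    stopf("`baseline_mean` must be positive")
  if (!is_scalar_number(dispersion) || dispersion < 0)
    stopf("`dispersion` must be nonnegative")
  defaults <- switch(response_class,
    downstream_nonlinear = list(A = 0.9, k = 5.3),
    downstream_linear = list(c = 0.5),
    compensatory_negative = list(gamma = 0.5),
    unresponsive = list())
  rc <- utils::modifyList(defaults, response_curve)
  structure(list(gene_id = as.character(gene_id),
                 response_class = response_class,
                 baseline_mean = baseline_mean,
                 response_curve = rc,
                 dispersion = dispersion),
            class = "gene_model")
}

#' Mean multiplier of a gene model at given expression levels
#'
#' @param model A [gene_model()].
#' @param eps Nonnegative expression values.
#' @return Positive multipliers (1 for unresponsive genes and at
#'   `eps = 1` for every class).
#' @export
gene_multiplier <- function(model, eps) {
  stopifnot(inherits(model, "gene_model"))
  if (any(eps < 0)) stopf("expression values must be nonnegative")
  rc <- model$response_curve
  switch(model$response_class,
    unresponsive = rep(1, length(eps)),
    downstream_nonlinear =
      (1 - rc$A * exp(-rc$k * eps)) / (1 - rc$A * exp(-rc$k)),
    downstream_linear = (rc$c + eps) / (rc$c + 1),
    compensatory_negative = exp(rc$gamma * (1 - eps)))
}

#' Default gene panel for synthetic counts
#'
#' @param n_unresponsive,n_nonlinear,n_linear,n_compensatory Number of
#'   genes per response class.
#' @param dispersion Common negative-binomial dispersion.
#' @param seed Seed for the (log-uniform) baseline means.
#' @return List of [gene_model()] objects.
#' @export
default_gene_models <- function(n_unresponsive = 300, n_nonlinear = 30,
                                n_linear = 20, n_compensatory = 5,
                                dispersion = 0.05, seed = 1L) {
  classes <- rep(c("unresponsive", "downstream_nonlinear",
                   "downstream_linear", "compensatory_negative"),
                 c(n_unresponsive, n_nonlinear, n_linear, n_compensatory))
  with_seed(seed, {
    base <- exp(stats::runif(length(classes), log(20), log(2000)))
    Map(function(i, cl, b)
      gene_model(sprintf("gene_%04d_%s", i, abbreviate(cl, 6)), cl,
                 baseline_mean = b, dispersion = dispersion),
      seq_along(classes), classes, base)
  })
}

#' Sample a synthetic RNA-seq count matrix for an allelic series
#'
#' Per sample: a true expression value drawn from its genotype's
#' truncated normal, a log-normal library factor (about two-fold range),
#' and per gene a negative-binomial count with mean
#' `baseline * multiplier(eps) * library_factor`.
#'
#' @param config A [series_config()] (>= 2 genotypes).
#' @param genes List of [gene_model()] (>= 1).
#' @param seed Integer seed.
#' @param n_per_genotype Samples per genotype (default 2, emulating a
#'   small RNA-seq design across the series).
#' @param library_log_sd SD of log library factors (default `log(2)/2`).
#' @return A list with `counts` (genes x samples integer matrix),
#'   `metadata` (sample_id, genotype, expression, library_factor), and
#'   `genes`.
#' @export
sample_counts <- function(config, genes = default_gene_models(),
                          seed = NULL, n_per_genotype = 2,
                          library_log_sd = log(2) / 2) {
  stopifnot(inherits(config, "series_config"))
  if (length(config$genotypes) < 2) stopf("need at least 2 genotypes")
  if (length(genes) < 1) stopf("need at least 1 gene")
  stopifnot(all(vapply(genes, inherits, TRUE, "gene_model")))
  with_seed(seed, {
    meta <- do.call(rbind, lapply(config$genotypes, function(g) {
      eps <- rtruncnorm(n_per_genotype,
                        truncnorm_spec(g$mean_expression, g$expression_sd))
      data.frame(sample_id = sprintf("%s_rna%d", g$name, seq_len(n_per_genotype)),
                 genotype = g$name, expression = eps,
                 stringsAsFactors = FALSE)
    }))
    meta$library_factor <- exp(stats::rnorm(nrow(meta), 0, library_log_sd))
    counts <- matrix(0L, length(genes), nrow(meta),
                     dimnames = list(vapply(genes, function(g) g$gene_id, ""),
                                     meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      mu <- vapply(genes, function(g)
        g$baseline_mean * gene_multiplier(g, meta$expression[j]), 1.0) *
        meta$library_factor[j]
      disp <- vapply(genes, function(g) g$dispersion, 1.0)
      pois <- disp < 1e-8
      cnt <- integer(length(mu))
      if (any(pois)) cnt[pois] <- stats::rpois(sum(pois), mu[pois])
      if (any(!pois)) cnt[!pois] <- stats::rnbinom(sum(!pois),
                                                   size = 1 / disp[!pois],
                                                   mu = mu[!pois])
      counts[, j] <- cnt
    }
    list(counts = counts, metadata = meta, genes = genes)
  })
}

#' Sample a triplicate qPCR Ct table for an allelic series
#'
#' Reference-gene Ct values are normal around a fixed mean; target Ct is
#' the reference mean plus an offset minus `log2(eps)` plus technical
#' noise, so the delta-delta-Ct pipeline recovers expression up to noise.
#'
#' @param config A [series_config()].
#' @param seed Integer seed.
#' @param target,reference Gene labels for the target and reference rows.
#' @param technical_sd Per-replicate technical noise SD (cycles).
#' @param ref_mean Mean reference-gene Ct.
#' @param offset Fixed target-minus-reference offset (cycles).
#' @param n_replicates Technical replicates per (sample, gene).
#' @return A list with `ct` (data.frame: sample_id, genotype, gene,
#'   replicate, ct) and `truth` (expression per sample).
#' @export
sample_qpcr <- function(config, seed = NULL, target = "Fgf8",
                        reference = "Gapdh", technical_sd = 0.1,
                        ref_mean = 20, offset = 5, n_replicates = 3) {
  stopifnot(inherits(config, "series_config"))
  with_seed(seed, {
    rows <- list(); truth <- list()
    for (g in config$genotypes) {
      eps <- rtruncnorm(g$n_individuals,
                        truncnorm_spec(g$mean_expression, g$expression_sd))
      for (i in seq_len(g$n_individuals)) {
        id <- sprintf("%s_%02d", g$name, i)
        ct_ref <- ref_mean + stats::rnorm(n_replicates, 0, technical_sd)
        eps_pos <- max(eps[i], 1e-6)   # Ct must stay finite
        ct_tgt <- ref_mean + offset - log2(eps_pos) +
          stats::rnorm(n_replicates, 0, technical_sd)
        rows[[id]] <- data.frame(
          sample_id = id, genotype = g$name,
          gene = rep(c(reference, target), each = n_replicates),
          replicate = rep(seq_len(n_replicates), 2),
          ct = c(ct_ref, ct_tgt), stringsAsFactors = FALSE)
        truth[[id]] <- data.frame(sample_id = id, genotype = g$name,
                                  expression = eps[i],
                                  stringsAsFactors = FALSE)
      }
    }
    list(ct = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

#' Sample a near-isogenic SNP panel
#'
#' Each line is fixed (dosage 0 or 2) at most loci; a fraction
#' `within_line_het` of loci segregate within the line with allele
#' frequency 0.5 (per-sample dosages Binomial(2, 0.5)).
#'
#' @param n_lines Number of inbred lines (>= 1).
#' @param n_loci Number of loci (>= 1).
#' @param within_line_het Fraction of loci segregating within each line.
#' @param seed Integer seed.
#' @param n_per_line Samples per line.
#' @param alt_freq Across-line frequency of the fixed alternate allele.
#' @return A list with `genotypes` (loci x samples matrix of 0/1/2),
#'   `line` (per-sample line labels), `locus_ids`.
#' @export
sample_snp_panel <- function(n_lines, n_loci, within_line_het = 0,
                             seed = NULL, n_per_line = 5, alt_freq = 0.3) {
  if (n_lines < 1 || n_loci < 1) stopf("need at least 1 line and 1 locus")
  if (within_line_het < 0 || within_line_het > 1)
    stopf("`within_line_het` must be in [0, 1]")
  with_seed(seed, {
    n_samples <- n_lines * n_per_line
    geno <- matrix(0L, n_loci, n_samples)
    line <- rep(sprintf("line%02d", seq_len(n_lines)), each = n_per_line)
    for (l in seq_len(n_lines)) {
      cols <- which(line == sprintf("line%02d", l))
      fixed <- 2L * stats::rbinom(n_loci, 1, alt_freq)
      geno[, cols] <- fixed
      n_het <- round(within_line_het * n_loci)
      if (n_het > 0) {
        het_loci <- sample.int(n_loci, n_het)
        geno[het_loci, cols] <- matrix(
          stats::rbinom(n_het * length(cols), 2, 0.5), n_het)
      }
    }
    rownames(geno) <- sprintf("snp%05d", seq_len(n_loci))
    colnames(geno) <- sprintf("%s_s%d", line,
                              rep(seq_len(n_per_line), n_lines))
    list(genotypes = geno, line = line, locus_ids = rownames(geno))
  })
}
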