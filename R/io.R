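# Plain-text readers and writers for the formats the analyses consume:
# wide-CSV landmark tables, TPS (LM3 records), counts TSV, Ct CSV, SNP
# CSV / minimal PLINK-style text, GMT gene sets, and YAML ground truth.

#' Write / read landmark configurations as wide CSV
#'
#' Columns: `specimen_id`, `genotype`, `lab`, `stage`, `size_covariate`,
#' then `x1,y1,z1,x2,...` for K landmarks.
#'
#' @param configs List of [landmark_configuration()].
#' @param path Output file.
#' @return `write_landmarks_csv` returns `path` invisibly;
#'   `read_landmarks_csv` returns a list of configurations.
#' @export
write_landmarks_csv <- function(configs, path) {
  stopifnot(all(vapply(configs, inherits, TRUE, "landmark_configuration")))
  k <- nrow(configs[[1]]$coords)
  coord_names <- as.vector(t(outer(seq_len(k), c("x", "y", "z"),
                                   function(i, a) paste0(a, i))))
  rows <- lapply(configs, function(cf) {
    out <- data.frame(specimen_id = cf$specimen_id,
                      genotype = as.character(cf$genotype),
                      lab = as.character(cf$lab),
                      stage = as.numeric(cf$stage),
                      size_covariate = as.numeric(cf$size_covariate),
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(t(flatten_shape(cf$coords)),
                             col.names = coord_names))
  })
  df <- do.call(rbind, rows)
  names(df)[-(1:5)] <- coord_names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  coord_cols <- setdiff(names(df), c("specimen_id", "genotype", "lab",
                                     "stage", "size_covariate"))
  lapply(seq_len(nrow(df)), function(i)
    landmark_configuration(unflatten_shape(as.numeric(df[i, coord_cols])),
                           df$specimen_id[i], df$genotype[i], df$lab[i],
                           df$stage[i], df$size_covariate[i]))
}

#' Write / read 3D landmarks in TPS format (LM3 records)
#'
#' @inheritParams write_landmarks_csv
#' @export
write_tps <- function(configs, path) {
  lines <- unlist(lapply(configs, function(cf) {
    c(sprintf("LM3=%d", nrow(cf$coords)),
      apply(cf$coords, 1, function(r) paste(format(r, digits = 10),
                                            collapse = " ")),
      sprintf("ID=%s", cf$specimen_id))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tps
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path))
  configs <- list(); i <- 1
  while (i <= length(lines)) {
    if (!grepl("^LM3=", lines[i])) stopf("malformed TPS file at line %d", i)
    k <- as.integer(sub("^LM3=", "", lines[i]))
    coords <- do.call(rbind, lapply(lines[(i + 1):(i + k)], function(l)
      as.numeric(strsplit(l, "\\s+")[[1]])))
    i <- i + k + 1
    id <- if (i <= length(lines) && grepl("^ID=", lines[i])) {
      id <- sub("^ID=", "", lines[i]); i <- i + 1; id
    } else sprintf("specimen_%d", length(configs) + 1)
    configs[[length(configs) + 1]] <- landmark_configuration(coords, id)
  }
  configs
}

#' Write / read a genes x samples count matrix as TSV
#'
#' First column `gene_id`, then one column per sample.
#' @param counts Genes x samples matrix.
#' @param path File path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a SNP genotype matrix from CSV
#'
#' Loci as rows (first column locus id), samples as columns; entries
#' 0/1/2 or empty for missing.
#' @param path File path.
#' @export
read_snp_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  .check_snp_matrix(m)
}

#' Read a minimal PLINK-style text genotype file
#'
#' Whitespace-separated with a header row of sample ids; each following
#' row is a locus id and per-sample dosages 0/1/2 (NA or -9 = missing).
#' @param path File path.
#' @export
read_snp_plink <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m[m == -9] <- NA
  .check_snp_matrix(m)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab
#' separated.
#' @param path File path.
#' @return List of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(l) {
    parts <- strsplit(l, "\t")[[1]]
    gene_set(parts[1], parts[-(1:2)])
  })
}

#' Write ground truth of a synthetic dataset as a YAML sidecar
#'
#' @param truth Data.frame of per-specimen ground truth.
#' @param config The generating [series_config()].
#' @param path Output file.
#' @export
write_ground_truth_yaml <- function(truth, config, path) {
  payload <- list(
    curve = list(L_m = config$curve$L_m, L_0 = config$curve$L_0,
                 k = config$curve$k),
    landmark_noise_sd = config$landmark_noise_sd,
    seed = config$seed,
    genotypes = lapply(config$genotypes, function(g)
      list(name = g$name, mean_expression = g$mean_expression,
           expression_sd = g$expression_sd,
           n_individuals = g$n_individuals)),
    specimens = lapply(seq_len(nrow(truth)), function(i) as.list(truth[i, ])))
  yaml::write_yaml(payload, path)
  invisible(path)
}
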