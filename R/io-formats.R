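# Readers and writers for the tool's file formats (TSV + BED), with strict
# validation: loaders reject malformed values rather than coercing them.
#
# Conventions (documented in the README): methylation and genotype files are
# feature-major (rows = CpGs / SNPs, columns = samples); sample columns are
# aligned to the samples table by ID, never by position; BED intervals are
# 0-based half-open.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# full-precision numeric formatting so write -> read is the identity
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

align_sample_columns <- function(M, samples, what) {
  if (is.null(samples)) return(M)
  ids <- samples$data$sample_id
  missing <- setdiff(ids, rownames(M))
  if (length(missing))
    stop_arg("%s file lacks sample(s): %s", what, paste(missing, collapse = ", "))
  unknown <- setdiff(rownames(M), ids)
  if (length(unknown))
    stop_arg("%s file has unknown sample_id(s): %s", what,
             paste(unknown, collapse = ", "))
  M[ids, , drop = FALSE]
}

#' Read the samples table
#'
#' TSV with header `sample_id`, `family_id`, `phenotype` plus covariate
#' columns.
#'
#' @param path TSV path.
#' @param covariates covariate columns to adjust for (default: all extra
#'   columns).
#' @return A [sample_frame()].
#' @export
read_samples <- function(path, covariates = NULL) {
  sample_frame(read_tsv_checked(path), covariates = covariates)
}

#' @rdname read_samples
#' @param frame a [sample_frame()] to write.
#' @export
write_samples <- function(frame, path) {
  write_tsv_precise(frame$data, path)
  invisible(path)
}

#' Read a methylation beta-value matrix with its CpG manifest
#'
#' The matrix file has rows = CpGs (first column `cpg_id`) and columns =
#' samples; the manifest has columns `cpg_id`, `chrom`, `pos`. Values are
#' validated to lie in `[0, 1]` with no missing entries.
#'
#' @param path matrix TSV path.
#' @param manifest_path manifest TSV path.
#' @param samples optional [sample_frame()]; sample columns are aligned to
#'   its order by `sample_id` (an unknown or absent ID is an error).
#' @return A [methylation_matrix()] (samples x CpGs orientation in memory).
#' @export
read_methylation <- function(path, manifest_path, samples = NULL) {
  df <- read_tsv_checked(path)
  if (names(df)[1] != "cpg_id")
    stop_arg("methylation file must have 'cpg_id' as its first column")
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(vals) <- df$cpg_id
  if (!is.numeric(vals)) stop_arg("non-numeric beta-values in %s", path)
  manifest <- read_tsv_checked(manifest_path)
  vals <- align_sample_columns(vals, samples, "methylation")
  methylation_matrix(vals, manifest)
}

#' @rdname read_methylation
#' @param meth a [methylation_matrix()] to write.
#' @export
write_methylation <- function(meth, path, manifest_path = NULL) {
  df <- data.frame(cpg_id = colnames(meth$values),
                   t(meth$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_precise(df, path)
  if (!is.null(manifest_path)) write_tsv_precise(meth$manifest, manifest_path)
  invisible(path)
}

#' Read an additive-coded genotype matrix
#'
#' Rows = SNPs (first column `snp_id`), columns = samples; values 0/1/2,
#' missing allowed (mean-imputed downstream by [compute_grm()]).
#'
#' @param path TSV path.
#' @param samples optional [sample_frame()] for column alignment by ID.
#' @return n x m numeric matrix (samples x SNPs).
#' @export
read_genotypes <- function(path, samples = NULL) {
  df <- read_tsv_checked(path)
  if (names(df)[1] != "snp_id")
    stop_arg("genotype file must have 'snp_id' as its first column")
  if (anyDuplicated(df$snp_id)) stop_arg("duplicate snp_id in %s", path)
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(vals) <- df$snp_id
  bad <- !(vals %in% c(0, 1, 2)) & !is.na(vals)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(vals)), arr.ind = TRUE)[1, ]
    stop_arg("genotype not in {0,1,2,NA} at sample '%s', SNP '%s'",
             rownames(vals)[idx[1]], colnames(vals)[idx[2]])
  }
  align_sample_columns(vals, samples, "genotype")
}

#' @rdname read_genotypes
#' @param genotypes samples x SNPs matrix to write.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(snp_id = colnames(genotypes), t(genotypes),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from BED
#'
#' Standard 3+1 columns (chrom, start, end, gene_id), no header, 0-based
#' half-open coordinates.
#'
#' @param path BED path.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop_arg("BED file needs 4 columns (chrom, start, end, gene_id)")
  genes <- data.frame(gene_id = as.character(df[[4]]),
                      chrom = as.character(df[[1]]),
                      start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop_arg("duplicate gene_id(s): %s",
             paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (any(genes$start >= genes$end))
    stop_arg("gene interval with start >= end: %s",
             paste(genes$gene_id[genes$start >= genes$end], collapse = ", "))
  if (any(genes$start < 0)) stop_arg("negative BED coordinates")
  genes
}

#' @rdname read_genes
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes[, c("chrom", "start", "end", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read/write a covariance matrix (e.g. a GRM) as TSV
#'
#' Sample IDs appear as both the header row and the first column.
#'
#' @param path TSV path.
#' @return n x n numeric matrix.
#' @export
read_grm <- function(path) {
  df <- read_tsv_checked(path)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- as.character(df[[1]])
  if (!identical(rownames(M), colnames(M)))
    stop_arg("GRM row and column sample IDs disagree")
  M
}

#' @rdname read_grm
#' @param grm matrix to write.
#' @export
write_grm <- function(grm, path) {
  df <- data.frame(sample_id = rownames(grm), grm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_precise(df, path)
  invisible(path)
}

#' Write scan results as TSV
#'
#' One row per annotated gene, with per-power and aSPUw p-values; scan
#' metadata goes to a sidecar JSON when `metadata_path` is given.
#'
#' @param scan an `aspuw_scan` from [run_scan()].
#' @param path output TSV path.
#' @param metadata_path optional JSON path for the scan metadata.
#' @export
write_results <- function(scan, path, metadata_path = NULL) {
  write_tsv_precise(scan$results, path)
  if (!is.null(metadata_path)) {
    meta <- scan$metadata
    meta$gammas <- gamma_labels(meta$gammas)
    jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Emits every file the scan pipeline reads (samples, methylation + manifest,
#' genotypes, genes BED) plus a JSON truth file recording the generating
#' parameters.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(samples = file.path(dir, "samples.tsv"),
             methylation = file.path(dir, "methylation.tsv"),
             manifest = file.path(dir, "manifest.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             genes = file.path(dir, "genes.bed"),
             truth = file.path(dir, "truth.json"))
  write_samples(dataset$samples, paths["samples"])
  write_methylation(dataset$methylation, paths["methylation"], paths["manifest"])
  write_genotypes(dataset$genotypes, paths["genotypes"])
  write_genes(dataset$genes, paths["genes"])
  truth <- dataset$truth
  truth$effects <- NULL
  truth$frame0 <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  paths
}
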