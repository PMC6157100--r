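# Prespecified covariance structures: empirical GRM and family blocks.

#' Estimate the genetic relationship matrix from SNP genotypes
#'
#' Standardized-genotype cross-product estimator:
#' `Psi[i,i'] = (1/m') sum_s z_is z_i's` with
#' `z_is = (g_is - 2 p_s) / sqrt(2 p_s (1 - p_s))`, where `p_s` is the sample
#' allele frequency of SNP `s` and `m'` the number of SNPs retained after
#' dropping monomorphic ones. Missing genotypes are mean-imputed per SNP
#' before standardization. The result is symmetrized and PSD-repaired by
#' clipping negative eigenvalues at zero (REML downstream needs a valid
#' covariance). A rowwise Pearson-correlation variant is available via
#' `method = "correlation"`.
#'
#' @param genotypes n x m numeric matrix of additive codes {0,1,2}; `NA`
#'   allowed. Rownames are sample IDs.
#' @param max_snps optionally subsample this many SNPs (without replacement)
#'   before estimation.
#' @param method `"standardized"` (default) or `"correlation"` (Pearson
#'   correlation between samples' standardized genotype profiles).
#' @param seed seed for the SNP subsample.
#' @return n x n symmetric PSD matrix with sample IDs as dimnames.
#' @export
compute_grm <- function(genotypes, max_snps = NULL,
                        method = c("standardized", "correlation"),
                        seed = NULL) {
  method <- match.arg(method)
  G <- as.matrix(genotypes)
  storage.mode(G) <- "double"
  if (nrow(G) < 2) stop_arg("GRM estimation needs at least 2 samples")
  ok_vals <- G %in% c(0, 1, 2) | is.na(G)
  if (!all(ok_vals)) stop_arg("genotypes must be coded 0/1/2 (NA allowed)")
  if (!is.null(max_snps) && max_snps < ncol(G)) {
    keep <- with_seed(seed, sample(ncol(G), max_snps))
    G <- G[, keep, drop = FALSE]
  }
  # mean-impute missing per SNP
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2]]
  }
  p_hat <- colMeans(G) / 2
  poly <- p_hat > 0 & p_hat < 1
  if (!any(poly)) stop_arg("all SNPs are monomorphic; cannot estimate a GRM")
  G <- G[, poly, drop = FALSE]
  p_hat <- p_hat[poly]
  Z <- sweep(G, 2, 2 * p_hat)
  Z <- sweep(Z, 2, sqrt(2 * p_hat * (1 - p_hat)), `/`)
  A <- if (method == "standardized") {
    tcrossprod(Z) / ncol(Z)
  } else {
    # correlation between samples' standardized profiles
    stats::cor(t(Z))
  }
  A <- psd_repair(A)$mat
  dimnames(A) <- list(rownames(genotypes), rownames(genotypes))
  A
}

#' Within-family block matrix
#'
#' Shared-environment covariance structure: 1 whenever two samples belong to
#' the same family (including the diagonal), 0 otherwise. Block-diagonal and
#' PSD by construction.
#'
#' @param family_ids per-sample family labels, in sample order.
#' @return n x n 0/1 matrix.
#' @export
#' @examples
#' family_block_matrix(c("A", "A", "B"))
family_block_matrix <- function(family_ids) {
  if (length(family_ids) == 0 || anyNA(family_ids))
    stop_arg("every sample needs a non-missing family label")
  f <- as.character(family_ids)
  M <- outer(f, f, `==`) + 0
  dimnames(M) <- list(names(family_ids), names(family_ids))
  M
}
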