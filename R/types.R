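# Core data containers (S3).

#' Construct a sample frame
#'
#' Bundles per-individual identifiers, family labels, the quantitative
#' phenotype and a full-rank fixed-effect design matrix (intercept always
#' included) for downstream mixed-model fitting.
#'
#' @param data data.frame with columns `sample_id`, `family_id`, `phenotype`
#'   plus any covariate columns.
#' @param covariates character vector of covariate column names to adjust for
#'   (default: every column other than `sample_id`, `family_id`, `phenotype`).
#' @return An object of class `sample_frame` with elements `data`, `y`
#'   (phenotype vector), `X` (n x q design matrix, first column the
#'   intercept), `covariates`.
#' @export
sample_frame <- function(data, covariates = NULL) {
  req <- c("sample_id", "family_id", "phenotype")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop_arg("samples table lacks column(s): %s",
                             paste(miss, collapse = ", "))
  data$sample_id <- as.character(data$sample_id)
  data$family_id <- as.character(data$family_id)
  if (anyDuplicated(data$sample_id))
    stop_arg("duplicate sample_id: %s",
             paste(unique(data$sample_id[duplicated(data$sample_id)]), collapse = ", "))
  if (anyNA(data$phenotype))
    stop_arg("missing phenotype for sample(s): %s",
             paste(data$sample_id[is.na(data$phenotype)], collapse = ", "))
  if (is.null(covariates))
    covariates <- setdiff(names(data), req)
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop_arg("unknown covariate column(s): %s",
                             paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  if (anyNA(X)) stop_arg("missing covariate values are not allowed")
  if (qr(X)$rank < ncol(X))
    stop_arg("covariate design matrix is rank deficient (q = %d, rank = %d)",
             ncol(X), qr(X)$rank)
  rownames(X) <- data$sample_id
  structure(list(data = data, y = stats::setNames(as.numeric(data$phenotype),
                                                  data$sample_id),
                 X = X, covariates = covariates),
            class = "sample_frame")
}

#' @export
print.sample_frame <- function(x, ...) {
  cat(sprintf("<sample_frame> %d samples in %d families; %d covariate(s): %s\n",
              nrow(x$data), length(unique(x$data$family_id)),
              length(x$covariates),
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "(intercept only)"))
  invisible(x)
}

#' Construct a methylation matrix with its CpG manifest
#'
#' @param values n x p numeric matrix of beta-values in `[0,1]`; rows are
#'   samples (rownames = sample IDs), columns are CpGs (colnames = CpG IDs).
#' @param manifest data.frame with columns `cpg_id`, `chrom`, `pos` (0-based
#'   position), one row per column of `values`, in matching order.
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(values, manifest) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) stop_arg("methylation matrix needs CpG column names")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop_arg("missing beta-value at sample row %d, CpG column %d", idx[1], idx[2])
  }
  bad <- values < 0 | values > 1
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_arg("beta-value outside [0,1] at sample row %d, CpG '%s' (value %g)",
             idx[1], colnames(values)[idx[2]], values[idx[1], idx[2]])
  }
  if (anyDuplicated(colnames(values)))
    stop_arg("duplicate CpG ids: %s",
             paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  req <- c("cpg_id", "chrom", "pos")
  if (!all(req %in% names(manifest)))
    stop_arg("manifest must have columns cpg_id, chrom, pos")
  manifest <- manifest[, req]
  manifest$cpg_id <- as.character(manifest$cpg_id)
  manifest$chrom <- as.character(manifest$chrom)
  manifest$pos <- as.integer(manifest$pos)
  if (!identical(manifest$cpg_id, colnames(values))) {
    if (!setequal(manifest$cpg_id, colnames(values)))
      stop_arg("manifest CpG ids do not match methylation columns")
    manifest <- manifest[match(colnames(values), manifest$cpg_id), ]
  }
  if (any(manifest$pos < 0)) stop_arg("manifest positions must be nonnegative")
  structure(list(values = values, manifest = manifest),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("<methylation_matrix> %d samples x %d CpGs on %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$manifest$chrom), collapse = ",")))
  invisible(x)
}

#' Bundle prespecified variance-component matrices
#'
#' Holds the K prespecified n x n PSD correlation-structure matrices
#' (e.g. a genetic relationship matrix and a within-family block matrix)
#' whose scalar multipliers are estimated by REML in [fit_null_lmm()].
#'
#' @param psis named list of symmetric n x n matrices.
#' @param check_psd if `TRUE` (default) verify the smallest eigenvalue of each
#'   matrix is above `-tol` before accepting it.
#' @param tol tolerance for the eigenvalue check.
#' @return An object of class `variance_components` with elements `psis`,
#'   `K`, and placeholders `T` (fitted components) and `sigma2` (residual
#'   variance) that [fit_null_lmm()] populates.
#' @export
variance_components <- function(psis, check_psd = TRUE, tol = 1e-8) {
  if (!is.list(psis) || length(psis) == 0L)
    stop_arg("psis must be a nonempty list of matrices")
  if (is.null(names(psis)) || any(names(psis) == ""))
    names(psis) <- paste0("psi", seq_along(psis))
  n <- nrow(psis[[1]])
  for (k in seq_along(psis)) {
    A <- psis[[k]]
    if (!is.matrix(A) || nrow(A) != n || ncol(A) != n)
      stop_arg("psi '%s' is not an %d x %d matrix", names(psis)[k], n, n)
    if (!is_symmetric(A))
      stop_arg("psi '%s' is not symmetric", names(psis)[k])
    psis[[k]] <- (A + t(A)) / 2
    if (check_psd) {
      lam_min <- min(eigen(psis[[k]], symmetric = TRUE, only.values = TRUE)$values)
      if (lam_min < -tol * max(1, max(abs(A))))
        stop_arg("psi '%s' has eigenvalue %g below the PSD tolerance",
                 names(psis)[k], lam_min)
    }
  }
  structure(list(psis = psis, K = length(psis), n = n,
                 T = rep(NA_real_, length(psis)), sigma2 = NA_real_),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> K = %d (%s), n = %d\n",
              x$K, paste(names(x$psis), collapse = ", "), x$n))
  if (!anyNA(x$T))
    cat(sprintf("  fitted T: %s; sigma2 = %.4g\n",
                paste(sprintf("%.4g", x$T), collapse = ", "), x$sigma2))
  invisible(x)
}

#' Specify true effect sizes for phenotype simulation
#'
#' @param alpha covariate effects (length q, matching the design matrix of the
#'   sample frame, intercept first).
#' @param beta per-CpG effects (length p, any sign; all zero gives an exact
#'   null generator).
#' @param T nonnegative variance components, one per prespecified matrix.
#' @param sigma2 residual variance, strictly positive.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(alpha, beta, T, sigma2) {
  if (any(T < 0)) stop_arg("variance components must be nonnegative")
  if (length(sigma2) != 1L || sigma2 <= 0) stop_arg("sigma2 must be > 0")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 T = as.numeric(T), sigma2 = as.numeric(sigma2)),
            class = "effect_spec")
}
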