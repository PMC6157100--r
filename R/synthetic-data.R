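# Synthetic family data: pedigrees, genotypes, methylation, phenotypes.
#
# These generators exist so the whole testing pipeline (GRM estimation, REML
# null fit, score extraction, SPUw/aSPUw Monte Carlo) can be validated
# end-to-end without access to any restricted cohort data.

#' Simulate nuclear-family pedigrees with their kinship matrix
#'
#' Families are nuclear: two unrelated founders plus `family_size - 2`
#' offspring (a family of size 1 is a lone founder, size 2 an unrelated
#' couple). The returned matrix holds additive relatedness coefficients
#' (twice the kinship coefficient): 1 on the diagonal, 0.5 for
#' parent-offspring and full-sib pairs, 0 across families.
#'
#' @param n_families number of families (>= 1).
#' @param family_size either a single size shared by all families, a vector of
#'   length `n_families` giving each family's size, or (with
#'   `size_probs`) a set of sizes sampled per family.
#' @param size_probs optional sampling probabilities when `family_size` is a
#'   set of candidate sizes.
#' @param seed optional integer seed (only used when sizes are sampled).
#' @return An object of class `pedigree`: a list with `samples` (data.frame:
#'   `sample_id`, `family_id`, `father_id`, `mother_id`) and `kinship`
#'   (n x n symmetric PSD relatedness matrix with unit diagonal).
#' @export
#' @examples
#' ped <- simulate_pedigree(2, 4)
#' ped$kinship
simulate_pedigree <- function(n_families, family_size = 4, size_probs = NULL,
                              seed = NULL) {
  if (length(n_families) != 1L || n_families < 1 || n_families != round(n_families))
    stop_arg("n_families must be a positive integer")
  if (any(family_size < 1) || any(family_size != round(family_size)))
    stop_arg("family sizes must be positive integers")
  sizes <- if (length(family_size) == 1L) {
    rep(as.integer(family_size), n_families)
  } else if (!is.null(size_probs) || length(family_size) != n_families) {
    with_seed(seed, sample(as.integer(family_size), n_families,
                           replace = TRUE, prob = size_probs))
  } else as.integer(family_size)

  rows <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    fid <- sprintf("F%04d", f)
    s <- sizes[f]
    ids <- sprintf("%s_I%d", fid, seq_len(s))
    father <- mother <- rep(NA_character_, s)
    if (s >= 3) {
      father[3:s] <- ids[1]
      mother[3:s] <- ids[2]
    }
    rows[[f]] <- data.frame(sample_id = ids, family_id = fid,
                            father_id = father, mother_id = mother,
                            stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  n <- nrow(samples)

  # additive relationship matrix by the tabular method, familywise
  kin <- matrix(0, n, n, dimnames = list(samples$sample_id, samples$sample_id))
  idx <- stats::setNames(seq_len(n), samples$sample_id)
  for (f in unique(samples$family_id)) {
    mem <- which(samples$family_id == f)
    for (i in mem) {
      fa <- samples$father_id[i]; mo <- samples$mother_id[i]
      if (is.na(fa)) {
        kin[i, i] <- 1
      } else {
        fi <- idx[[fa]]; mi <- idx[[mo]]
        kin[i, i] <- 1 + 0.5 * kin[fi, mi]
        for (j in mem[mem < i]) {
          kin[i, j] <- kin[j, i] <- 0.5 * (kin[j, fi] + kin[j, mi])
        }
      }
    }
  }
  structure(list(samples = samples, kinship = kin), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d individuals in %d families\n",
              nrow(x$samples), length(unique(x$samples$family_id))))
  invisible(x)
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founders receive two independent alleles per SNP at a minor-allele
#' frequency drawn uniformly from `maf_range`; offspring inherit one randomly
#' chosen allele from each parent (Mendelian transmission), so realized
#' relatedness matches the pedigree in expectation.
#'
#' @param pedigree a `pedigree` from [simulate_pedigree()] (parental links are
#'   required for transmission, which the kinship matrix alone cannot supply).
#' @param m_snps number of SNPs (>= 1).
#' @param maf_range length-2 interval inside (0, 0.5] from which per-SNP MAFs
#'   are drawn.
#' @param seed optional integer seed.
#' @return n x m integer matrix of additive genotype codes {0,1,2}, rownames
#'   sample IDs, colnames SNP IDs.
#' @export
simulate_genotypes <- function(pedigree, m_snps, maf_range = c(0.05, 0.5),
                               seed = NULL) {
  if (!inherits(pedigree, "pedigree")) stop_arg("pedigree must come from simulate_pedigree()")
  if (m_snps < 1) stop_arg("m_snps must be >= 1")
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop_arg("maf_range must lie within (0, 0.5]")
  samples <- pedigree$samples
  n <- nrow(samples)
  m <- as.integer(m_snps)
  with_seed(seed, {
    maf <- stats::runif(m, maf_range[1], maf_range[2])
    hap1 <- matrix(0L, n, m)
    hap2 <- matrix(0L, n, m)
    idx <- stats::setNames(seq_len(n), samples$sample_id)
    for (i in seq_len(n)) {
      fa <- samples$father_id[i]
      if (is.na(fa)) {
        hap1[i, ] <- stats::rbinom(m, 1L, maf)
        hap2[i, ] <- stats::rbinom(m, 1L, maf)
      } else {
        fi <- idx[[fa]]; mi <- idx[[samples$mother_id[i]]]
        pick <- stats::runif(m) < 0.5
        hap1[i, ] <- ifelse(pick, hap1[fi, ], hap2[fi, ])
        pick <- stats::runif(m) < 0.5
        hap2[i, ] <- ifelse(pick, hap1[mi, ], hap2[mi, ])
      }
    }
    geno <- hap1 + hap2
    dimnames(geno) <- list(samples$sample_id,
                           sprintf("snp%06d", seq_len(m)))
    geno
  })
}

#' Simulate correlated methylation beta-values
#'
#' Latent Gaussians with exchangeable correlation `rho` across the p CpGs are
#' mapped through the inverse logit, with per-CpG latent scales chosen (delta
#' method) so empirical beta-value standard deviations track
#' `variance_profile`. Heterogeneous per-CpG variability is what makes the
#' inverse-standard-deviation weighting differ from constant weights, so the
#' profile is required.
#'
#' @param n number of samples.
#' @param p_cpgs number of CpG sites.
#' @param within_gene_corr latent exchangeable correlation, in `[0, 1)`.
#' @param variance_profile length-p vector of target beta-value standard
#'   deviations (> 0).
#' @param mean_logit length-1 or length-p latent means (0 puts CpG means at
#'   beta = 0.5).
#' @param seed optional integer seed.
#' @return n x p matrix of beta-values in `[0, 1]`, colnames `cpg_...`. The
#'   latent construction is invertible: `qlogis(values)` recovers the
#'   Gaussians exactly, which the tests exploit to check the correlation.
#' @export
simulate_methylation <- function(n, p_cpgs, within_gene_corr = 0,
                                 variance_profile, mean_logit = 0,
                                 seed = NULL) {
  if (n < 1 || p_cpgs < 1) stop_arg("dimensions must be positive")
  rho <- within_gene_corr
  if (length(rho) != 1L || rho < 0 || rho >= 1)
    stop_arg("within_gene_corr must lie in [0, 1)")
  if (length(variance_profile) == 1L)
    variance_profile <- rep(variance_profile, p_cpgs)
  if (length(variance_profile) != p_cpgs || any(variance_profile <= 0))
    stop_arg("variance_profile must be a positive vector of length p_cpgs")
  mu <- rep(mean_logit, length.out = p_cpgs)
  pm <- stats::plogis(mu)
  scale <- variance_profile / (pm * (1 - pm)) # delta-method latent SD
  with_seed(seed, {
    shared <- stats::rnorm(n)
    Z <- sqrt(rho) * shared +
      sqrt(1 - rho) * matrix(stats::rnorm(n * p_cpgs), n, p_cpgs)
    vals <- stats::plogis(sweep(Z, 2, scale, `*`) + rep(mu, each = n))
    colnames(vals) <- sprintf("cpg%05d", seq_len(p_cpgs))
    vals
  })
}

#' Simulate phenotypes from the linear mixed model
#'
#' Draws `y = X alpha + G beta + b + e` with the random intercept
#' `b ~ N(0, sum_k T_k Psi_k)` and `e ~ iid N(0, sigma2)`. With `beta = 0`
#' this is an exact null generator for the association tests. The covariance
#' factorization is computed once, so many replicates are cheap.
#'
#' @param frame a [sample_frame()] providing the design matrix `X` (its
#'   phenotype column is ignored).
#' @param G n x p methylation matrix (or `methylation_matrix`); may be `NULL`
#'   when `beta` is empty.
#' @param effects an [effect_spec()].
#' @param psis a [variance_components()] holding the K matrices multiplied by
#'   `effects$T`.
#' @param seed optional integer seed.
#' @param n_replicates number of independent phenotype vectors to draw.
#' @return numeric vector (default) or n x `n_replicates` matrix.
#' @export
simulate_phenotype <- function(frame, G = NULL, effects, psis = NULL,
                               seed = NULL, n_replicates = 1) {
  X <- frame$X
  n <- nrow(X)
  if (inherits(G, "methylation_matrix")) G <- G$values
  alpha <- effects$alpha
  beta <- effects$beta
  if (length(alpha) != ncol(X))
    stop_arg("alpha has length %d but X has %d columns", length(alpha), ncol(X))
  if (length(beta) > 0) {
    if (is.null(G) || ncol(G) != length(beta) || nrow(G) != n)
      stop_arg("G must be an n x length(beta) matrix")
  }
  Tk <- effects$T
  if (!is.null(psis)) {
    if (length(Tk) != psis$K)
      stop_arg("effects$T has length %d but psis has K = %d", length(Tk), psis$K)
    if (psis$n != n) stop_arg("psis dimension does not match sample size")
  } else if (any(Tk > 0)) {
    stop_arg("psis must be supplied when any T_k > 0")
  }

  mean_part <- drop(X %*% alpha)
  if (length(beta) > 0) mean_part <- mean_part + drop(G %*% beta)

  Lb <- NULL
  if (!is.null(psis) && any(Tk > 0)) {
    Omega <- Reduce(`+`, Map(`*`, Tk, psis$psis))
    rep_ <- psd_repair(Omega)
    pos <- rep_$values > 0
    # factor with only the positive spectrum; rank can be << n
    Lb <- rep_$vectors[, pos, drop = FALSE] *
      rep(sqrt(rep_$values[pos]), each = n)
  }
  with_seed(seed, {
    R <- as.integer(n_replicates)
    b <- if (is.null(Lb)) matrix(0, n, R)
         else Lb %*% matrix(stats::rnorm(ncol(Lb) * R), ncol(Lb), R)
    eps <- matrix(stats::rnorm(n * R, sd = sqrt(effects$sigma2)), n, R)
    y <- mean_part + b + eps
    rownames(y) <- rownames(X)
    if (R == 1L) drop(y) else y
  })
}

#' Simulate a complete family methylation study
#'
#' One-stop generator used by the tests, the acceptance studies and the
#' `simulate` CLI subcommand: pedigree, gene-dropped genotypes, an empirical
#' GRM plus family-block variance-component set, genes laid out along one
#' chromosome with correlated CpGs, covariates (one continuous age-like, one
#' binary sex-like), and a mixed-model phenotype. Per-stage seeds are derived
#' deterministically from the master seed.
#'
#' @param n_families,family_size passed to [simulate_pedigree()].
#' @param n_genes number of genes; each gets `cpgs_per_gene` CpGs.
#' @param cpgs_per_gene CpGs per gene.
#' @param m_snps SNP count for genotype simulation / GRM estimation.
#' @param within_gene_corr latent CpG correlation within a gene.
#' @param variance_profile_range range of per-CpG target beta-value SDs;
#'   profiles are spaced evenly across each gene (heterogeneous by design).
#' @param alpha fixed effects: intercept, age-like, sex-like.
#' @param beta named list mapping gene index to its length-`cpgs_per_gene`
#'   effect vector; genes not listed have zero effects.
#' @param T length-2 variance components for (GRM, family blocks).
#' @param sigma2 residual variance.
#' @param grm_source `"empirical"` (default; GRM estimated from the simulated
#'   SNPs via [compute_grm()]) or `"pedigree"` (true kinship matrix).
#' @param seed master seed.
#' @return list with `samples` ([sample_frame()]), `methylation`
#'   ([methylation_matrix()]), `genotypes`, `genes` (data.frame gene_id,
#'   chrom, start, end), `psis` ([variance_components()]), `pedigree`, and
#'   `truth` (all generating parameters).
#' @export
simulate_dataset <- function(n_families = 200, family_size = 4, n_genes = 1,
                             cpgs_per_gene = 10, m_snps = 2000,
                             within_gene_corr = 0.5,
                             variance_profile_range = c(0.02, 0.12),
                             alpha = c(0, 0.5, 0.3),
                             beta = list(),
                             T = c(0.3, 0.2), sigma2 = 1,
                             grm_source = c("empirical", "pedigree"),
                             seed = 1) {
  grm_source <- match.arg(grm_source)
  ped <- simulate_pedigree(n_families, family_size,
                           seed = derive_seed(seed, "pedigree"))
  n <- nrow(ped$samples)
  geno <- simulate_genotypes(ped, m_snps, seed = derive_seed(seed, "genotypes"))
  grm <- if (grm_source == "empirical") compute_grm(geno) else ped$kinship
  psis <- variance_components(
    list(grm = grm,
         family = family_block_matrix(ped$samples$family_id)),
    check_psd = FALSE)

  p <- n_genes * cpgs_per_gene
  profile <- rep(seq(variance_profile_range[1], variance_profile_range[2],
                     length.out = cpgs_per_gene), n_genes)
  # each gene is an independent exchangeable block
  vals <- matrix(NA_real_, n, p)
  for (g in seq_len(n_genes)) {
    cols <- (g - 1) * cpgs_per_gene + seq_len(cpgs_per_gene)
    vals[, cols] <- simulate_methylation(
      n, cpgs_per_gene, within_gene_corr,
      profile[cols], seed = derive_seed(seed, paste0("meth", g)))
  }
  cpg_ids <- sprintf("cg%07d", seq_len(p))
  colnames(vals) <- cpg_ids
  rownames(vals) <- ped$samples$sample_id

  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  gene_span <- 200L * (as.integer(cpgs_per_gene) + 1L)
  starts <- 10000L * seq_len(n_genes)
  genes <- data.frame(gene_id = gene_ids, chrom = "chr1",
                      start = starts, end = starts + gene_span,
                      stringsAsFactors = FALSE)
  pos <- as.integer(rep(starts, each = cpgs_per_gene) +
                      200L * rep(seq_len(cpgs_per_gene), n_genes))
  manifest <- data.frame(cpg_id = cpg_ids, chrom = "chr1", pos = pos,
                         stringsAsFactors = FALSE)
  meth <- methylation_matrix(vals, manifest)

  cov_seed <- derive_seed(seed, "covariates")
  covs <- with_seed(cov_seed, data.frame(
    age = stats::rnorm(n), sex = stats::rbinom(n, 1, 0.5)))

  beta_full <- numeric(p)
  for (nm in names(beta)) {
    g <- as.integer(nm)
    cols <- (g - 1) * cpgs_per_gene + seq_len(cpgs_per_gene)
    beta_full[cols] <- beta[[nm]]
  }

  sf0 <- sample_frame(cbind(data.frame(sample_id = ped$samples$sample_id,
                                       family_id = ped$samples$family_id,
                                       phenotype = 0), covs))
  eff <- effect_spec(alpha = alpha, beta = beta_full, T = T, sigma2 = sigma2)
  y <- simulate_phenotype(sf0, vals, eff, psis,
                          seed = derive_seed(seed, "phenotype"))
  sf <- sample_frame(cbind(data.frame(sample_id = ped$samples$sample_id,
                                      family_id = ped$samples$family_id,
                                      phenotype = y), covs))
  list(samples = sf, methylation = meth, genotypes = geno, genes = genes,
       psis = psis, pedigree = ped,
       truth = list(alpha = alpha, beta = beta_full, T = T, sigma2 = sigma2,
                    within_gene_corr = within_gene_corr,
                    variance_profile = profile, grm_source = grm_source,
                    seed = seed, effects = eff, frame0 = sf0))
}
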