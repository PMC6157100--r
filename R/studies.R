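# Simulation-study drivers: type-I error calibration, power comparisons,
# and REML parameter recovery on synthetic family data. These power the
# package's validation suite and the reproducibility script, and are exported
# because designing such studies is routine when adopting an adaptive test.

study_structure <- function(n_families, family_size, p_cpgs, rho,
                            variance_profile_range, T, sigma2, seed) {
  simulate_dataset(n_families = n_families, family_size = family_size,
                   n_genes = 1, cpgs_per_gene = p_cpgs, m_snps = 2000,
                   within_gene_corr = rho,
                   variance_profile_range = variance_profile_range,
                   T = T, sigma2 = sigma2, seed = seed)
}

fit_replicate <- function(frame_data, y, psis, init) {
  f <- sample_frame(transform(frame_data, phenotype = y))
  fit_null_lmm(f, psis = psis, n_starts = 1, init = init,
               control = list(rhobeg = 0.25, rhoend = 1e-2, grad_check = FALSE))
}

#' Monte Carlo study of SPUw/aSPUw behavior under the mixed-model generator
#'
#' Simulates `n_replicates` phenotypes from the family mixed model (null when
#' `beta = 0`, alternative otherwise), refits the null model by REML for each
#' replicate, and computes SPUw and aSPUw Monte Carlo p-values for the single
#' simulated gene, for one or both weighting modes (both modes share the
#' same scores and null draws, so comparisons are paired).
#'
#' @param n_families,family_size pedigree layout (nuclear families).
#' @param p_cpgs CpGs in the simulated gene.
#' @param rho latent within-gene correlation of the beta-values.
#' @param variance_profile_range range of per-CpG beta-value SDs (evenly
#'   spaced, heterogeneous).
#' @param T,sigma2 generating variance components (GRM, family) and residual
#'   variance.
#' @param beta length-`p_cpgs` CpG effect vector (0 = null calibration).
#' @param n_replicates phenotype replicates.
#' @param B Monte Carlo null draws per test.
#' @param gammas powers for the SPUw family.
#' @param weights weighting modes to evaluate.
#' @param seed master seed.
#' @return list: `pvalues` — a named list per weighting mode, each an
#'   `n_replicates` x (|gammas| + 1) matrix of p-values (columns per power
#'   plus `aspuw`); `rejections(alpha)` via [study_rejection_rates()];
#'   `structure` — the simulated dataset skeleton.
#' @export
aspuw_power_study <- function(n_families = 200, family_size = 4, p_cpgs = 10,
                              rho = 0.5, variance_profile_range = c(0.02, 0.12),
                              T = c(0.3, 0.2), sigma2 = 1,
                              beta = numeric(p_cpgs), n_replicates = 1000,
                              B = 500, gammas = c(1:6, Inf),
                              weights = c("inverse_sd", "constant"),
                              seed = 1) {
  d <- study_structure(n_families, family_size, p_cpgs, rho,
                       variance_profile_range, T, sigma2,
                       derive_seed(seed, "structure"))
  G <- d$methylation$values
  eff <- effect_spec(d$truth$alpha, beta, T, sigma2)
  Y <- simulate_phenotype(d$truth$frame0, G, eff, d$psis,
                          seed = derive_seed(seed, "phenotypes"),
                          n_replicates = n_replicates)
  omegas <- lapply(stats::setNames(weights, weights),
                   function(w) compute_weights(G, w))
  labs <- c(gamma_labels(gammas), "aspuw")
  pvals <- lapply(omegas, function(.)
    matrix(NA_real_, n_replicates, length(labs),
           dimnames = list(NULL, labs)))
  init <- T / sigma2
  for (r in seq_len(n_replicates)) {
    fit <- fit_replicate(d$samples$data, Y[, r], d$psis, init)
    init <- pmax(fit$delta, 1e-6) # warm-start the next replicate
    sv <- score_statistics(fit, G)
    seed_r <- derive_seed(seed, paste0("mc", r))
    for (w in names(omegas)) {
      res <- spuw_pvalues(sv$U, sv$V, omegas[[w]], gammas, B, seed_r)
      pvals[[w]][r, ] <- c(res$table$p_value, res$p_aspuw)
    }
  }
  list(pvalues = pvals, structure = d, gammas = gammas, B = B,
       beta = beta, seed = seed)
}

#' Rejection rates from a power/size study
#'
#' @param study result of [aspuw_power_study()].
#' @param alpha significance level.
#' @return named list per weighting mode of rejection-rate vectors (one entry
#'   per power plus `aspuw`).
#' @export
study_rejection_rates <- function(study, alpha = 0.05) {
  lapply(study$pvalues, function(P) colMeans(P <= alpha))
}

#' REML parameter-recovery study
#'
#' Repeatedly simulates phenotypes from known variance components on one
#' simulated family structure and refits them, returning the estimates.
#'
#' @param n_replicates number of phenotype replicates.
#' @param n_families,family_size pedigree layout.
#' @param T,sigma2 generating values.
#' @param seed master seed.
#' @return `n_replicates` x 3 matrix of estimates (`T1`, `T2`, `sigma2`).
#' @export
reml_recovery_study <- function(n_replicates = 50, n_families = 250,
                                family_size = 4, T = c(0.5, 0.3),
                                sigma2 = 1, seed = 1) {
  d <- study_structure(n_families, family_size, p_cpgs = 2, rho = 0,
                       variance_profile_range = c(0.05, 0.1),
                       T = T, sigma2 = sigma2,
                       seed = derive_seed(seed, "structure"))
  eff <- effect_spec(d$truth$alpha, numeric(0), T, sigma2)
  Y <- simulate_phenotype(d$truth$frame0, NULL, eff, d$psis,
                          seed = derive_seed(seed, "phenotypes"),
                          n_replicates = n_replicates)
  init <- T / sigma2
  out <- matrix(NA_real_, n_replicates, 3,
                dimnames = list(NULL, c("T1", "T2", "sigma2")))
  for (r in seq_len(n_replicates)) {
    fit <- fit_replicate(d$samples$data, Y[, r], d$psis, init)
    init <- pmax(fit$delta, 1e-6)
    out[r, ] <- c(fit$T, fit$sigma2)
  }
  out
}

#' Planted-signal scan study
#'
#' Simulates a multi-gene dataset in which one gene carries a dense CpG
#' effect and all others are null, runs the genome-wide scan, and reports
#' whether the planted gene attains the minimum aSPUw p-value together with
#' the genomic-control lambda of the null genes.
#'
#' @param n_genes total genes (one of which is causal).
#' @param causal_gene index of the planted gene.
#' @param beta_causal effect vector for the planted gene's CpGs.
#' @param n_families,family_size,cpgs_per_gene,rho layout.
#' @param T,sigma2 generating variance parameters.
#' @param B per-gene Monte Carlo draws for the first stage.
#' @param B_max staged-escalation cap; the default lets genes near the
#'   resolution floor separate from the best null order statistics.
#' @param seed master seed.
#' @return list: `scan`, `planted_gene`, `planted_is_min` (non-strict),
#'   `lambda_null` (lambda over the other genes), `null_pvalues`.
#' @export
planted_scan_study <- function(n_genes = 200, causal_gene = 1,
                               beta_causal = rep(2, 5), n_families = 150,
                               family_size = 4, cpgs_per_gene = 5,
                               rho = 0.5, T = c(0.3, 0.2), sigma2 = 1,
                               B = 1000, B_max = 100 * B, seed = 1) {
  d <- simulate_dataset(n_families = n_families, family_size = family_size,
                        n_genes = n_genes, cpgs_per_gene = cpgs_per_gene,
                        m_snps = 2000, within_gene_corr = rho,
                        T = T, sigma2 = sigma2,
                        beta = stats::setNames(list(beta_causal),
                                               as.character(causal_gene)),
                        seed = seed)
  scan <- run_scan(d$samples, d$methylation, d$psis, d$genes, B = B,
                   B_max = B_max, seed = derive_seed(seed, "scan"))
  res <- scan$results
  gid <- d$genes$gene_id[causal_gene]
  p_causal <- res$p_aspuw[res$gene_id == gid]
  null_p <- res$p_aspuw[res$testable & res$gene_id != gid]
  list(scan = scan, planted_gene = gid,
       planted_is_min = p_causal <= min(res$p_aspuw[res$testable]),
       p_causal = p_causal, null_pvalues = null_p,
       lambda_null = genomic_lambda(null_p))
}
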