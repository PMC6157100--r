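# Shared simulated fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# 60 nuclear families of 4, 3 genes x 5 CpGs, null phenotype
small_dataset <- function() memo("small", function() {
  simulate_dataset(n_families = 60, family_size = 4, n_genes = 3,
                   cpgs_per_gene = 5, m_snps = 600, seed = 101)
})

small_fit <- function() memo("small_fit", function() {
  d <- small_dataset()
  fit_null_lmm(d$samples, psis = d$psis, n_starts = 1, init = c(0.3, 0.2))
})

# null calibration study at the reference design (200 nuclear families of 4,
# 10 correlated CpGs with heterogeneous variances, GRM + family components);
# shared between the size and uniformity checks
calibration_study <- function() memo("calibration", function() {
  aspuw_power_study(n_families = 200, family_size = 4, p_cpgs = 10,
                    rho = 0.5, variance_profile_range = c(0.02, 0.12),
                    T = c(0.3, 0.2), sigma2 = 1, beta = numeric(10),
                    n_replicates = 1000, B = 500, weights = "inverse_sd",
                    seed = 20260926)
})

# brute-force Monte Carlo p-values by double loops, used as the independent
# oracle for the counting formulas
brute_mc_pvalues <- function(t_obs, t_null) {
  B <- nrow(t_null)
  p_spuw <- vapply(seq_along(t_obs), function(j)
    (1 + sum(abs(t_null[, j]) >= abs(t_obs[j]))) / (B + 1), numeric(1))
  p_null <- matrix(NA_real_, B, length(t_obs))
  for (b1 in seq_len(B)) for (j in seq_along(t_obs))
    p_null[b1, j] <- sum(abs(t_null[-b1, j]) >= abs(t_null[b1, j])) / B
  T_aspuw <- min(p_spuw)
  list(p_spuw = p_spuw, T_aspuw = T_aspuw,
       p_aspuw = (1 + sum(apply(p_null, 1, min) <= T_aspuw)) / (B + 1))
}
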