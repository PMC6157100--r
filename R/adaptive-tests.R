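# SPUw(gamma) statistics, Monte Carlo p-values, and the adaptive (aSPUw)
# minimum-p combination.

row_max_abs <- function(M) do.call(pmax, as.data.frame(abs(M)))

check_gammas <- function(gammas) {
  if (length(gammas) == 0) stop_arg("gamma set must be nonempty")
  finite <- is.finite(gammas)
  if (any(gammas[finite] < 1 | gammas[finite] != round(gammas[finite])))
    stop_arg("gammas must be positive integers or Inf")
  if (anyDuplicated(gammas)) stop_arg("duplicate gammas")
  gammas
}

gamma_labels <- function(gammas) ifelse(is.finite(gammas),
                                        as.character(gammas), "inf")

#' Per-CpG weights for the SPUw statistic
#'
#' Inverse-standard-deviation weights `omega_j = 1 / sd(G_j)` up-weight CpGs
#' with small variability; constant weights `omega_j = 1` recover the
#' unweighted SPU family.
#'
#' @param G n x p matrix of beta-values (or [methylation_matrix()]).
#' @param mode `"inverse_sd"` (default) or `"constant"`.
#' @return named numeric p-vector with attribute `mode`.
#' @export
compute_weights <- function(G, mode = c("inverse_sd", "constant")) {
  mode <- match.arg(mode)
  if (inherits(G, "methylation_matrix")) G <- G$values
  G <- as.matrix(G)
  omega <- if (mode == "constant") {
    rep(1, ncol(G))
  } else {
    s <- apply(G, 2, stats::sd)
    if (any(s <= 0))
      stop_arg("zero-variance CpG(s) reached weighting: %s",
               paste(colnames(G)[s <= 0], collapse = ", "))
    1 / s
  }
  names(omega) <- colnames(G)
  attr(omega, "mode") <- mode
  omega
}

#' Sum of powered weighted scores
#'
#' `T_SPUw(gamma) = sum_j (omega_j U_j)^gamma` for finite `gamma`;
#' `gamma = Inf` gives the limiting form `max_j |omega_j U_j|`.
#'
#' @param U score p-vector.
#' @param omega weight p-vector (or scalar, recycled).
#' @param gamma positive integer power, or `Inf`.
#' @return scalar statistic.
#' @export
#' @examples
#' spuw_statistic(c(1, 2, -1), 1, 2) # == 6, the U'U (linear-kernel) statistic
spuw_statistic <- function(U, omega, gamma) {
  check_gammas(gamma)
  if (length(gamma) != 1L) stop_arg("gamma must be a single power")
  w <- rep_len(omega, length(U)) * U
  if (!all(is.finite(w))) stop_arg("non-finite weighted scores")
  if (is.finite(gamma)) sum(w^gamma) else max(abs(w))
}

#' Simulate null score vectors
#'
#' Draws `B` independent copies `U^(b) ~ N(0, V)` through a symmetric
#' eigenfactorization of `V`, with negative eigenvalues clipped at zero
#' (rank-deficient `V` is expected for correlated CpGs).
#'
#' @param V p x p symmetric covariance with smallest eigenvalue above
#'   `-1e-8` (scaled).
#' @param B number of draws.
#' @param seed optional integer seed.
#' @return B x p matrix of null scores.
#' @export
simulate_null_scores <- function(V, B, seed = NULL) {
  V <- as.matrix(V)
  if (!is_symmetric(V)) stop_arg("V must be symmetric")
  if (B < 1) stop_arg("B must be >= 1")
  p <- ncol(V)
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  lam <- e$values
  if (min(lam) < -1e-8 * max(1, max(abs(lam))))
    stop_arg("V has eigenvalue %g below the PSD tolerance", min(lam))
  lam[lam < max(lam, 0) * 1e-12] <- 0
  A <- e$vectors * rep(sqrt(lam), each = p) # V^(1/2), p x p
  with_seed(seed, matrix(stats::rnorm(B * p), as.integer(B), p) %*% t(A))
}

#' Monte Carlo p-values from observed and null SPUw statistics
#'
#' The counting engine shared by all tests. Per power: the two-sided
#' `P_SPUw(gamma) = [1 + sum_b I(|T^(b)| >= |T|)] / (B + 1)`. The adaptive
#' statistic is `T_aSPUw = min_gamma P_SPUw(gamma)`; each null replicate gets
#' leave-one-out per-power p-values
#' `p_gamma^(b1) = sum_{b != b1} I(|T^(b)| >= |T^(b1)|) / B`, minimized over
#' the powers, and `P_aSPUw = [1 + sum_b I(T_aSPUw^(b) <= T_aSPUw)] / (B+1)`.
#' Ties count toward significance (the indicators are `>=` / `<=`).
#'
#' @param t_obs named numeric vector of observed statistics, one per power.
#' @param t_null B x length(t_obs) matrix of null statistics computed from
#'   the same shared null score draws.
#' @return list: `p_spuw` (per-power p-values), `T_aspuw`, `p_aspuw`,
#'   `p_null_min` (the B leave-one-out minimum p-values), `B`.
#' @export
spuw_pvalues_from_stats <- function(t_obs, t_null) {
  t_null <- as.matrix(t_null)
  if (ncol(t_null) != length(t_obs))
    stop_arg("t_null must have one column per observed statistic")
  B <- nrow(t_null)
  a_null <- abs(t_null)
  p_spuw <- (1 + colSums(a_null >= rep(abs(t_obs), each = B))) / (B + 1)
  names(p_spuw) <- names(t_obs)
  # leave-one-out p-values via ranks: count of |T^(b)| >= |T^(b1)| among
  # b != b1 equals B - rank_min(b1)
  p_null <- apply(a_null, 2, function(col)
    (B - rank(col, ties.method = "min")) / B)
  if (B == 1L) p_null <- matrix(p_null, nrow = 1L)
  p_null_min <- do.call(pmin, as.data.frame(p_null))
  T_aspuw <- min(p_spuw)
  p_aspuw <- (1 + sum(p_null_min <= T_aspuw)) / (B + 1)
  list(p_spuw = p_spuw, T_aspuw = T_aspuw, p_aspuw = p_aspuw,
       p_null_min = p_null_min, B = B)
}

spuw_stats_matrix <- function(scores, omega, gammas) {
  W <- sweep(as.matrix(scores), 2, rep_len(omega, ncol(scores)), `*`)
  out <- matrix(NA_real_, nrow(W), length(gammas),
                dimnames = list(NULL, gamma_labels(gammas)))
  for (j in seq_along(gammas)) {
    out[, j] <- if (is.finite(gammas[j])) rowSums(W^gammas[j])
                else row_max_abs(W)
  }
  out
}

#' SPUw and aSPUw Monte Carlo p-values for one gene
#'
#' Simulates `B` null score vectors `U^(b) ~ N(0, V)` once, shares them
#' across all powers in `gammas` (required for the joint minimum-p null),
#' and applies the counting formulas of [spuw_pvalues_from_stats()].
#'
#' @param U observed score p-vector (from [score_statistics()]).
#' @param V its p x p null covariance.
#' @param omega weight vector (from [compute_weights()]).
#' @param gammas set of powers, e.g. `c(1:6, Inf)`.
#' @param B Monte Carlo replicates; all p-values live in `[1/(B+1), 1]`.
#' @param seed optional integer seed (bit-reproducible results).
#' @return An object of class `aspuw_result`: `table` (data.frame with
#'   columns `gamma`, `statistic`, `p_value`), `T_aspuw`, `p_aspuw`, `B`,
#'   `gammas`, `weight_mode`, `seed`, `n_cpgs`.
#' @export
spuw_pvalues <- function(U, V, omega, gammas = c(1:6, Inf), B = 1000,
                         seed = NULL) {
  check_gammas(gammas)
  if (B < length(gammas))
    warning(sprintf("B = %d is below |Gamma| = %d; aSPUw p-value resolution is very coarse",
                    B, length(gammas)), call. = FALSE)
  t_obs <- vapply(gammas, function(g) spuw_statistic(U, omega, g), numeric(1))
  names(t_obs) <- gamma_labels(gammas)
  draws <- simulate_null_scores(V, B, seed)
  t_null <- spuw_stats_matrix(draws, omega, gammas)
  mc <- spuw_pvalues_from_stats(t_obs, t_null)
  structure(list(
    table = data.frame(gamma = gamma_labels(gammas), statistic = unname(t_obs),
                       p_value = unname(mc$p_spuw), stringsAsFactors = FALSE),
    T_aspuw = mc$T_aspuw, p_aspuw = mc$p_aspuw, B = as.integer(B),
    gammas = gammas, weight_mode = attr(omega, "mode"), seed = seed,
    n_cpgs = length(U)), class = "aspuw_result")
}

#' @export
print.aspuw_result <- function(x, ...) {
  cat(sprintf("<aspuw_result> %d CpGs, B = %d, weights: %s\n",
              x$n_cpgs, x$B, x$weight_mode %||% "custom"))
  print(x$table, row.names = FALSE)
  cat(sprintf("  aSPUw: T = %.4g, p = %.4g\n", x$T_aspuw, x$p_aspuw))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adaptive SPUw test for one gene
#'
#' Convenience composition: per-CpG weights, score extraction against the
#' cached null fit, and Monte Carlo SPUw/aSPUw p-values. An optional staged
#' scheme rescales `B` upward (x10, up to `B_max`) whenever the smallest
#' p-value hits the resolution floor (`< 5/B`), so genome-wide scans can
#' resolve small p-values without paying maximal `B` everywhere.
#'
#' @param fit a [fit_null_lmm()] object.
#' @param G n x p beta-value matrix for the gene's CpGs (or a
#'   [methylation_matrix()]).
#' @param weight `"inverse_sd"` or `"constant"`.
#' @param gammas powers to combine (default `c(1:6, Inf)`).
#' @param B Monte Carlo replicates for the first stage.
#' @param B_max cap for staged escalation (default: no escalation).
#' @param seed optional integer seed.
#' @return An [spuw_pvalues()] result, with `n_cpgs`, `dropped` and the
#'   final `B` recorded.
#' @export
aspuw_test <- function(fit, G, weight = c("inverse_sd", "constant"),
                       gammas = c(1:6, Inf), B = 1000, B_max = B,
                       seed = NULL) {
  weight <- match.arg(weight)
  sv <- score_statistics(fit, G)
  if (inherits(G, "methylation_matrix")) G <- G$values
  omega <- compute_weights(as.matrix(G)[, sv$cpg_ids, drop = FALSE], weight)
  B_cur <- as.integer(B)
  seed_cur <- seed
  repeat {
    res <- spuw_pvalues(sv$U, sv$V, omega, gammas, B_cur, seed_cur)
    min_p <- min(res$table$p_value, res$p_aspuw)
    if (B_cur >= B_max || min_p >= 5 / B_cur) break
    B_cur <- as.integer(min(B_cur * 10, B_max))
    seed_cur <- if (is.null(seed)) NULL
                else derive_seed(seed, paste0("stageB", B_cur))
  }
  res$dropped <- sv$dropped
  res$seed <- seed
  res
}
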