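test_that("SPUw statistics follow the powered-sum definition", {
  U <- c(1, 2, -1)
  expect_equal(spuw_statistic(U, 1, 1), 2)
  expect_equal(spuw_statistic(U, 1, 2), 6)
  expect_equal(spuw_statistic(U, 1, 2), drop(crossprod(U))) # linear-kernel SKAT
  expect_equal(spuw_statistic(c(1, 1, 1), c(1, 0.5, 2), Inf), 2)
  expect_equal(spuw_statistic(U, c(2, 0.5, 1), 3), 8 + 1 - 1)
  set.seed(1)
  U2 <- rnorm(12)
  expect_identical(spuw_statistic(U2, 1, 2), sum(U2^2))
  expect_error(spuw_statistic(U, 1, 0), "positive integers")
  expect_error(spuw_statistic(U, 1, 1.5), "positive integers")
})

test_that("weights are reciprocal standard deviations (or constant)", {
  G <- cbind(a = c(0, 1, 0, 1) * 0.8, b = rep(c(0.2, 0.4), 2))
  # sample variance 4 -> weight 0.5, scaled down to beta range
  Gv <- matrix(rnorm(300, 0.5, 0.1), 100, 3,
               dimnames = list(NULL, c("x", "y", "z")))
  w <- compute_weights(Gv)
  expect_equal(as.numeric(w), unname(1 / apply(Gv, 2, sd)))
  expect_equal(attr(w, "mode"), "inverse_sd")
  wc <- compute_weights(Gv, "constant")
  expect_equal(as.numeric(wc), rep(1, 3))
  expect_error(compute_weights(cbind(Gv, flat = rep(0.3, 100))),
               "zero-variance")
  # direct arithmetic check: sd 2 -> weight 0.5 (scaled into [0,1] not needed
  # for the pure function)
  Gs <- cbind(v = c(0, 4, 0, 4, 0, 4, 0, 4) / 4)
  expect_equal(as.numeric(compute_weights(Gs)), 1 / sd(Gs[, 1]))
})

test_that("null score simulation factorizes V correctly", {
  expect_error(simulate_null_scores(matrix(c(1, 2, 0, 1), 2), 10), "symmetric")
  expect_equal(simulate_null_scores(matrix(0, 3, 3), 5, seed = 1),
               matrix(0, 5, 3))
  Z <- simulate_null_scores(diag(4), 20000, seed = 2)
  expect_true(all(abs(apply(Z, 2, var) - 1) < 3 / sqrt(20000) * 1.5))
  expect_lt(abs(cor(Z[, 1], Z[, 2])), 0.03)
  # rank-1 V = vv': every draw proportional to v
  v <- c(1, -2, 0.5)
  D <- simulate_null_scores(tcrossprod(v), 50, seed = 3)
  for (b in 1:50) {
    expect_equal(D[b, ] / v, rep(D[b, 1] / v[1], 3), tolerance = 1e-10)
  }
  expect_identical(simulate_null_scores(diag(3), 7, seed = 9),
                   simulate_null_scores(diag(3), 7, seed = 9))
})

test_that("Monte Carlo counting formulas are exact on injected statistics", {
  # observed |T| = 5 against null |T| = (1,2,3,4): P = (1+0)/5
  mc <- spuw_pvalues_from_stats(c(g1 = 5), cbind(c(1, 2, 3, 4)))
  expect_equal(unname(mc$p_spuw), 0.2)
  # observed |T| = 2.5: P = (1+2)/5
  mc2 <- spuw_pvalues_from_stats(c(g1 = 2.5), cbind(c(1, 2, 3, 4)))
  expect_equal(unname(mc2$p_spuw), 0.6)
  # signed statistics are compared in absolute value
  mc3 <- spuw_pvalues_from_stats(c(g1 = -2.5), cbind(c(-1, 2, -3, 4)))
  expect_equal(unname(mc3$p_spuw), 0.6)
  # ties count toward significance
  mc4 <- spuw_pvalues_from_stats(c(g1 = 3), cbind(c(1, 2, 3, 4)))
  expect_equal(unname(mc4$p_spuw), (1 + 2) / 5)

  # full engine (per-power, leave-one-out, min-p) against a brute-force
  # double-loop oracle on random inputs, including ties
  set.seed(44)
  for (rep in 1:5) {
    B <- 25
    t_null <- matrix(round(rnorm(B * 3), 1), B, 3)
    t_obs <- c(a = 0.4, b = round(rnorm(1), 1), c = 2)
    mc <- spuw_pvalues_from_stats(t_obs, t_null)
    oracle <- brute_mc_pvalues(t_obs, t_null)
    expect_equal(unname(mc$p_spuw), oracle$p_spuw)
    expect_equal(mc$T_aspuw, oracle$T_aspuw)
    expect_equal(mc$p_aspuw, oracle$p_aspuw)
  }
})

test_that("single-CpG genes give identical p-values for every power", {
  # with p = 1 and shared draws, |w U^(b)|^g >= |w U|^g is the same event
  # for every g > 0
  res <- spuw_pvalues(U = 1.7, V = matrix(2), omega = 0.8,
                      gammas = c(1:6, Inf), B = 500, seed = 12)
  expect_equal(length(unique(res$table$p_value)), 1L)
  expect_gte(res$p_aspuw, res$table$p_value[1])
})

test_that("p-values are bounded, deterministic, and scale-equivariant", {
  fit <- small_fit()
  d <- small_dataset()
  G <- d$methylation$values[, 1:5]
  r1 <- aspuw_test(fit, G, B = 400, seed = 21)
  r2 <- aspuw_test(fit, G, B = 400, seed = 21)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$p_aspuw, r2$p_aspuw)
  expect_true(all(r1$table$p_value >= 1 / 401 & r1$table$p_value <= 1))
  expect_gte(r1$p_aspuw, 1 / 401)

  # multiplying all weights by c > 0 leaves every p-value bit-identical
  sv <- score_statistics(fit, G)
  omega <- compute_weights(G)
  pa <- spuw_pvalues(sv$U, sv$V, omega, B = 300, seed = 5)
  pb <- spuw_pvalues(sv$U, sv$V, omega * 3.7, B = 300, seed = 5)
  expect_identical(pa$table$p_value, pb$table$p_value)
  expect_identical(pa$p_aspuw, pb$p_aspuw)

  # constant mode reduces to the unweighted SPU test
  pc <- spuw_pvalues(sv$U, sv$V, compute_weights(G, "constant"),
                     B = 300, seed = 5)
  pu <- spuw_pvalues(sv$U, sv$V, rep(1, 5), B = 300, seed = 5)
  expect_identical(pc$table, pu$table)

  expect_warning(spuw_pvalues(sv$U, sv$V, omega, B = 5, seed = 1),
                 "resolution")
})

test_that("staged escalation raises B only when the p-value hits the floor", {
  d <- small_dataset()
  # plant a strong dense signal on gene 1's CpGs
  G <- d$methylation$values[, 1:5]
  eff <- effect_spec(d$truth$alpha, rep(4, 5), d$truth$T, 1)
  y <- simulate_phenotype(d$truth$frame0, G, eff, d$psis, seed = 31)
  f <- sample_frame(transform(d$samples$data, phenotype = y))
  fit <- fit_null_lmm(f, psis = d$psis, n_starts = 1,
                      control = list(grad_check = FALSE))
  res <- aspuw_test(fit, G, B = 100, B_max = 10000, seed = 7)
  expect_equal(res$B, 10000L)
  expect_lt(res$p_aspuw, 0.01)
  # without a raised cap, B never escalates
  res0 <- aspuw_test(fit, G, B = 100, seed = 7)
  expect_equal(res0$B, 100L)
})
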