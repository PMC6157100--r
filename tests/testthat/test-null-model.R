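test_that("forcing all variance ratios to zero reproduces OLS", {
  set.seed(31)
  n <- 120
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- drop(X %*% c(1, 0.5, -0.3)) + rnorm(n)
  psis <- variance_components(list(blk = family_block_matrix(rep(1:30, each = 4))))
  fit <- fit_null_lmm(y, X, psis, delta = c(0))
  ols <- stats::lm.fit(X, y)
  expect_equal(unname(fit$alpha), unname(ols$coefficients), tolerance = 1e-10)
  expect_equal(fit$sigma2, sum(ols$residuals^2) / (n - 3), tolerance = 1e-10)
  expect_equal(fit$T, 0)
  # no-random-effect fit gives the same
  fit0 <- fit_null_lmm(y, X)
  expect_equal(fit0$alpha, fit$alpha, tolerance = 1e-10)
})

test_that("identity-matrix component is aliased with the residual but total variance is identified", {
  set.seed(32)
  n <- 150
  X <- cbind(1, rnorm(n))
  y <- rnorm(n, sd = sqrt(2))
  psis <- variance_components(list(iden = diag(n)))
  fit <- fit_null_lmm(y, X, psis, n_starts = 1)
  ols <- stats::lm.fit(X, y)
  s2_ols <- sum(ols$residuals^2) / (n - 2)
  # sigma2 + T1 (the only identified combination) equals the OLS variance
  expect_equal(fit$sigma2 + fit$T, s2_ols, tolerance = 1e-6)
  expect_equal(unname(fit$alpha), unname(ols$coefficients), tolerance = 1e-8)
})

test_that("fitted model satisfies the GLS normal equations and input contracts", {
  fit <- small_fit()
  expect_true(fit$converged)
  # X' Sigma^-1 (y - X alpha) = 0
  expect_lt(max(abs(crossprod(fit$X, fit$Sigma_inv_resid))), 1e-6)
  d <- small_dataset()
  expect_error(fit_null_lmm(d$samples$y, d$samples$X[, c(1, 2, 1)], d$psis),
               "rank deficient")
  expect_error(fit_null_lmm(d$samples$y[1:10], d$samples$X, d$psis), "rows")
})

test_that("REML recovers generating variance components at moderate scale", {
  d <- small_dataset() # truth: T = (0.3, 0.2), sigma2 = 1, n = 240
  ests <- sapply(1:5, function(r) {
    y <- simulate_phenotype(d$truth$frame0, d$methylation, d$truth$effects,
                            d$psis, seed = 4000 + r)
    f <- sample_frame(transform(d$samples$data, phenotype = y))
    fit <- fit_null_lmm(f, psis = d$psis, n_starts = 1, init = c(0.3, 0.2),
                        control = list(grad_check = FALSE))
    c(fit$T, fit$sigma2)
  })
  m <- rowMeans(ests)
  expect_lt(abs(m[1] - 0.3), 0.2)
  expect_lt(abs(m[2] - 0.2), 0.2)
  expect_lt(abs(m[3] - 1.0), 0.2)
})

test_that("score vector obeys its closed forms and invariances", {
  fit <- small_fit()
  d <- small_dataset()
  n <- fit$n

  # a CpG equal to a covariate column has exactly zero score
  Gx <- cbind(x1 = fit$X[, 2], cg = d$methylation$values[, 1])
  sv <- score_statistics(fit, Gx)
  expect_lt(abs(sv$U["x1"]), 1e-8 * sqrt(sv$V["x1", "x1"]) + 1e-10)

  # with Sigma = I (OLS fit) and intercept-only X:
  # sigma2 * U_j = centered cross-product sum_i G_ij (y_i - ybar)
  y <- d$samples$y
  fit_iid <- fit_null_lmm(y, matrix(1, n, 1))
  G <- d$methylation$values[, 1:4]
  sv_iid <- score_statistics(fit_iid, G)
  expect_equal(fit_iid$sigma2 * sv_iid$U,
               drop(crossprod(G, y - mean(y))), tolerance = 1e-10,
               ignore_attr = TRUE)

  # V is symmetric PSD
  expect_true(isSymmetric(sv_iid$V))
  expect_gte(min(eigen(sv_iid$V, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)

  # affine reparameterization of X leaves (U, V) unchanged (fixed ratios
  # make the comparison exact)
  A <- rbind(c(1, 0.5, -1), c(0, 2, 1), c(0, 0, 3))
  fit1 <- fit_null_lmm(y, fit$X, d$psis, delta = c(0.25, 0.1))
  fit2 <- fit_null_lmm(y, fit$X %*% A, d$psis, delta = c(0.25, 0.1))
  sv1 <- score_statistics(fit1, G)
  sv2 <- score_statistics(fit2, G)
  expect_equal(sv1$U, sv2$U, tolerance = 1e-8)
  expect_equal(sv1$V, sv2$V, tolerance = 1e-8)

  # scores depend on y only through the GLS residual: shifting y by X c
  # changes alpha-hat but not (U, V)
  fit3 <- fit_null_lmm(y + drop(fit$X %*% c(2, -1, 3)), fit$X, d$psis,
                       delta = c(0.25, 0.1))
  sv3 <- score_statistics(fit3, G)
  expect_equal(sv1$U, sv3$U, tolerance = 1e-8)

  # zero-variance CpGs are dropped with a warning; all-constant gene errors
  Gz <- cbind(G, flat = rep(0.4, n))
  expect_warning(svz <- score_statistics(fit, Gz), "zero-variance")
  expect_equal(svz$cpg_ids, colnames(G))
  expect_error(suppressWarnings(score_statistics(fit, matrix(0.3, n, 2))),
               class = "aspuwscan_empty_gene")
})

test_that("empirical covariance of null scores matches the analytic V", {
  d <- small_dataset()
  fit <- small_fit()
  G <- d$methylation$values[, 1:5]
  # U = (PG)' y is linear in y; simulate y under the fitted null
  L <- fit$chol_H
  SiG <- backsolve(L, backsolve(L, G, transpose = TRUE)) / fit$sigma2
  PG <- SiG - fit$Sigma_inv_X %*% (fit$XtSiX_inv %*% crossprod(fit$X, SiG))
  eff <- effect_spec(fit$alpha, numeric(0), fit$T, fit$sigma2)
  Y <- simulate_phenotype(d$truth$frame0, NULL, eff, d$psis,
                          seed = 77, n_replicates = 4000)
  Umat <- crossprod(PG, Y) # p x R
  V_emp <- stats::cov(t(Umat))
  sv <- score_statistics(fit, G)
  scale <- sqrt(diag(sv$V) %o% diag(sv$V))
  expect_lt(max(abs(V_emp - sv$V) / scale), 0.12)
})
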