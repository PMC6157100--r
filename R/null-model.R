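# Gaussian linear mixed null model: REML fit and score statistics.
#
# The null model is y = X alpha + b + e with b ~ N(0, sum_k T_k Psi_k) and
# e ~ N(0, sigma2 I). Variance components are profiled: with
# delta_k = T_k / sigma2 and H(delta) = I + sum_k delta_k Psi_k, the REML
# criterion reduces to a K-dimensional optimization over log(delta), each
# evaluation costing one Cholesky of H. The fit is done once per phenotype;
# per-gene work is only score extraction against cached factors.

# -2 * restricted log-likelihood (up to an additive constant), profiled over
# alpha and sigma2. Returns the pieces needed to reconstruct the fit.
reml_profile <- function(delta, y, X, psi_list) {
  n <- length(y); q <- ncol(X)
  H <- NULL
  for (k in seq_along(psi_list)) {
    if (delta[k] == 0) next
    H <- if (is.null(H)) delta[k] * psi_list[[k]] else H + delta[k] * psi_list[[k]]
  }
  if (is.null(H)) H <- diag(n) else diag(H) <- diag(H) + 1
  L <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(L)) return(list(obj = Inf))
  ys <- backsolve(L, y, transpose = TRUE)
  Xs <- backsolve(L, X, transpose = TRUE)
  XtHX <- crossprod(Xs)
  cX <- chol(XtHX)
  Xty <- crossprod(Xs, ys)
  alpha <- backsolve(cX, backsolve(cX, Xty, transpose = TRUE))
  rss <- sum(ys^2) - drop(crossprod(Xty, alpha))
  sigma2 <- rss / (n - q)
  obj <- (n - q) * log(sigma2) + 2 * sum(log(diag(L))) +
    2 * sum(log(diag(cX)))
  list(obj = obj, sigma2 = sigma2, alpha = drop(alpha), L = L, cX = cX)
}

#' Fit the Gaussian linear mixed null model by REML
#'
#' Estimates the variance components `T_k` (one per prespecified matrix in
#' `psis`), the residual variance `sigma2`, and the GLS fixed effects
#' `alpha`, maximizing the restricted likelihood over the variance ratios
#' `T_k / sigma2` on the log scale (bounded quasi-Newton, by default three
#' dispersed starts, best objective kept). A residual variance term
#' `sigma2 * I` is always included in addition to the listed matrices. The
#' returned object caches the factorized covariance so that per-gene score
#' extraction via [score_statistics()] is cheap.
#'
#' @param y phenotype vector, or a [sample_frame()] (then `X` is taken from
#'   it and must not be supplied).
#' @param X n x q full-rank fixed-effect design matrix including the
#'   intercept.
#' @param psis a [variance_components()] object, or `NULL` for an ordinary
#'   least-squares fit (no random effects).
#' @param delta optional fixed variance ratios `T_k / sigma2`; skips the
#'   REML optimization (e.g. `delta = c(0, 0)` forces all `T_k = 0`, giving
#'   exactly the OLS fit).
#' @param init optional starting ratios for the first optimizer start.
#' @param n_starts number of dispersed starting points (1-3). The default 3
#'   guards against plateaus; 1 is adequate (and faster) for well-conditioned
#'   designs such as repeated simulation fits, especially with `init` warm
#'   starts.
#' @param control list: `method` — `"bobyqa"` (default; bounded
#'   derivative-free quadratic-model optimization, as lme4 uses for linear
#'   mixed models, with `rhobeg`/`rhoend` trust-region radii), `"L-BFGS-B"`
#'   (bounded quasi-Newton with finite-difference gradients; `factr`,
#'   `ndeps`) or `"Nelder-Mead"` (`reltol`); `maxit`; `grad_check` (default
#'   `TRUE`) computes the central-difference gradient norm at the optimum.
#' @return An object of class `null_model_fit`: fixed effects `alpha`,
#'   components `T` and `sigma2`, ratios `delta`, restricted log-likelihood
#'   `logLik`, `converged` flag, `grad_norm` (on the log-variance-ratio
#'   scale, interior coordinates only), plus cached GLS quantities.
#' @export
fit_null_lmm <- function(y, X = NULL, psis = NULL, delta = NULL, init = NULL,
                         n_starts = 3, control = list()) {
  if (inherits(y, "sample_frame")) {
    if (!is.null(X)) stop_arg("X is taken from the sample_frame; do not supply both")
    X <- y$X
    y <- y$y
  }
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y); q <- ncol(X)
  if (nrow(X) != n) stop_arg("X has %d rows but y has length %d", nrow(X), n)
  if (n <= q) stop_arg("need n > q (n = %d, q = %d)", n, q)
  if (qr(X)$rank < q) stop_arg("X is rank deficient")
  psi_list <- if (is.null(psis)) list() else psis$psis
  K <- length(psi_list)
  if (K > 0 && nrow(psi_list[[1]]) != n)
    stop_arg("psi dimension %d does not match n = %d", nrow(psi_list[[1]]), n)

  ctrl <- utils::modifyList(list(method = "bobyqa", factr = 1e9,
                                 reltol = 1e-8, ndeps = 1e-4, maxit = 200,
                                 rhobeg = 0.3, rhoend = 1e-5,
                                 grad_check = TRUE, lower = -18, upper = 8),
                            control)
  converged <- TRUE
  grad_norm <- NA_real_
  opt_counts <- c(0L, 0L)

  if (K == 0L || (!is.null(delta) && all(delta == 0))) {
    delta_hat <- rep(0, K)
  } else if (!is.null(delta)) {
    if (length(delta) != K || any(delta < 0))
      stop_arg("delta must be %d nonnegative ratios", K)
    delta_hat <- as.numeric(delta)
  } else {
    fn <- function(ld) reml_obj_cpp(exp(ld), y, X, psi_list)
    starts <- list(log(rep(0.4, K)), log(rep(0.05, K)), log(rep(2, K)))
    if (!is.null(init)) {
      ld0 <- log(pmax(as.numeric(init), 1e-8))
      starts <- c(list(pmin(pmax(ld0, ctrl$lower), ctrl$upper)), starts)
    }
    starts <- starts[seq_len(max(1, min(n_starts + !is.null(init), length(starts))))]
    best <- NULL
    for (s in starts) {
      opt <- if (ctrl$method == "bobyqa") {
        o <- minqa::bobyqa(s, fn, lower = rep(ctrl$lower, K),
                           upper = rep(ctrl$upper, K),
                           control = list(rhobeg = ctrl$rhobeg,
                                          rhoend = ctrl$rhoend))
        list(par = o$par, value = o$fval, convergence = o$ierr,
             counts = c(o$feval, 0L))
      } else if (ctrl$method == "L-BFGS-B") {
        stats::optim(s, fn, method = "L-BFGS-B",
                     lower = ctrl$lower, upper = ctrl$upper,
                     control = list(factr = ctrl$factr, maxit = ctrl$maxit,
                                    ndeps = rep(ctrl$ndeps, K)))
      } else {
        o <- stats::optim(s, fn, method = ctrl$method,
                          control = list(reltol = ctrl$reltol,
                                         maxit = ctrl$maxit))
        o$par <- pmin(pmax(o$par, ctrl$lower), ctrl$upper)
        o
      }
      opt_counts <- opt_counts + ifelse(is.na(opt$counts), 0L, opt$counts)
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    converged <- best$convergence == 0L
    ld_hat <- best$par
    if (ctrl$grad_check) {
      h <- 1e-4
      interior <- ld_hat > ctrl$lower + 2 * h & ld_hat < ctrl$upper - 2 * h
      if (any(interior)) {
        g <- vapply(which(interior), function(k) {
          e <- numeric(K); e[k] <- h
          (fn(ld_hat + e) - fn(ld_hat - e)) / (2 * h)
        }, numeric(1))
        grad_norm <- sqrt(sum(g^2))
      } else grad_norm <- 0
    }
    delta_hat <- exp(ld_hat)
    delta_hat[ld_hat <= ctrl$lower + 1e-10] <- 0
  }

  prof <- reml_profile(delta_hat, y, X, psi_list)
  if (!is.finite(prof$obj)) stop("REML objective is not finite at the optimum",
                                 call. = FALSE)
  sigma2 <- prof$sigma2
  alpha <- stats::setNames(prof$alpha, colnames(X))
  T_hat <- sigma2 * delta_hat
  resid <- y - drop(X %*% prof$alpha)
  L <- prof$L
  # H^{-1} r and H^{-1} X via the cached Cholesky factor of H
  Hi_resid <- backsolve(L, backsolve(L, resid, transpose = TRUE))
  HiX <- backsolve(L, backsolve(L, X, transpose = TRUE))
  XtSiX <- crossprod(X, HiX) / sigma2
  fit <- structure(list(
    alpha = alpha, T = T_hat, sigma2 = sigma2, delta = delta_hat, K = K,
    psi_names = names(psi_list),
    logLik = -0.5 * (prof$obj + (n - q) * (1 + log(2 * pi))),
    converged = converged, grad_norm = grad_norm,
    n = n, q = q, n_evals = unname(opt_counts[1]),
    sample_ids = if (!is.null(rownames(X))) rownames(X) else names(y),
    y = y, X = X, resid = resid,
    chol_H = L, Sigma_inv_resid = Hi_resid / sigma2,
    Sigma_inv_X = HiX / sigma2, XtSiX = XtSiX,
    XtSiX_inv = chol2inv(chol(XtSiX))), class = "null_model_fit")
  if (!is.null(psis)) {
    psis$T <- T_hat
    psis$sigma2 <- sigma2
    fit$psis <- psis
  }
  fit
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf("<null_model_fit> n = %d, q = %d; restricted logLik = %.2f\n",
              x$n, x$q, x$logLik))
  comps <- if (x$K > 0) paste(sprintf("%s = %.4g", x$psi_names, x$T),
                              collapse = ", ") else "(none)"
  cat(sprintf("  variance components: %s; sigma2 = %.4g\n", comps, x$sigma2))
  cat(sprintf("  converged: %s (|grad| = %.2g on log-ratio scale)\n",
              x$converged, x$grad_norm))
  invisible(x)
}

#' Extract the score vector and its covariance for a gene's CpGs
#'
#' For the CpG matrix `G` of one gene, computes the Gaussian score evaluated
#' at the null fit, `U = G' Sigma^-1 (y - X alpha)`, and its null covariance
#' with fixed effects profiled out,
#' `V = G' P G`, `P = Sigma^-1 - Sigma^-1 X (X' Sigma^-1 X)^-1 X' Sigma^-1`,
#' using the plug-in REML estimates of `(T, sigma2)`. CpGs with zero sample
#' variance are dropped with a warning before computation.
#'
#' @param fit a converged [fit_null_lmm()] object.
#' @param G n x p numeric matrix of beta-values (or a
#'   [methylation_matrix()]); rows must be in (or reorderable by rowname to)
#'   the fit's sample order.
#' @return An object of class `score_vector`: `U` (named p-vector), `V`
#'   (p x p symmetric), `cpg_ids`, `dropped` (IDs of zero-variance CpGs),
#'   `n`.
#' @export
score_statistics <- function(fit, G) {
  if (inherits(G, "methylation_matrix")) G <- G$values
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (nrow(G) != fit$n)
    stop_arg("G has %d rows but the fit has n = %d", nrow(G), fit$n)
  if (!is.null(rownames(G)) && !is.null(fit$sample_ids) &&
      !identical(rownames(G), fit$sample_ids)) {
    if (!setequal(rownames(G), fit$sample_ids))
      stop_arg("G row names do not match the fitted samples")
    G <- G[fit$sample_ids, , drop = FALSE]
  }
  if (is.null(colnames(G))) colnames(G) <- paste0("cpg", seq_len(ncol(G)))
  v <- apply(G, 2, stats::var)
  dropped <- colnames(G)[v <= 0]
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance CpG(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
    G <- G[, v > 0, drop = FALSE]
  }
  if (ncol(G) == 0L)
    stop(structure(class = c("aspuwscan_empty_gene", "error", "condition"),
                   list(message = "no testable CpGs after filtering",
                        call = sys.call(-1))))
  U <- drop(crossprod(G, fit$Sigma_inv_resid))
  L <- fit$chol_H
  SiG <- backsolve(L, backsolve(L, G, transpose = TRUE)) / fit$sigma2
  XtSiG <- crossprod(fit$X, SiG)
  V <- crossprod(G, SiG) - crossprod(XtSiG, fit$XtSiX_inv %*% XtSiG)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(G), colnames(G))
  structure(list(U = U, V = V, cpg_ids = colnames(G), dropped = dropped,
                 n = fit$n), class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> p = %d CpGs (n = %d)\n", length(x$U), x$n))
  invisible(x)
}
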