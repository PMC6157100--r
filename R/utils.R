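# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package functions do
#' not disturb the global random stream. A `NULL` seed evaluates the
#' expression under the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and a string key
#'
#' Deterministic 31-bit hash so that per-gene (or per-operation) random
#' streams are reproducible and independent of processing order.
#'
#' @param master integer master seed.
#' @param key character scalar naming the stream (e.g. a gene ID).
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "GENE001")
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(key), length(key) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- abs(as.numeric(master)) %% m
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Symmetrize and clip negative eigenvalues of a covariance matrix
#'
#' @param A square matrix, nominally symmetric PSD up to numerical error.
#' @param tol eigenvalues below `-tol * max(1, |lambda|_max)` trigger a repair
#'   message; all negative eigenvalues are clipped at 0.
#' @return list with `mat` (repaired matrix) and `rank` (number of positive
#'   eigenvalues).
#' @noRd
psd_repair <- function(A, tol = 1e-8) {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  lam <- e$values
  neg <- lam < 0
  if (any(neg)) {
    lam[neg] <- 0
    A <- e$vectors %*% (lam * t(e$vectors))
    A <- (A + t(A)) / 2
  }
  list(mat = A, rank = sum(lam > max(lam, 0) * 1e-12), values = lam,
       vectors = e$vectors)
}

is_symmetric <- function(A, tol = 1e-8) {
  is.matrix(A) && nrow(A) == ncol(A) &&
    max(abs(A - t(A))) <= tol * max(1, max(abs(A)))
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)
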