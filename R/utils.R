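# Internal numerical helpers shared across the package.

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix (max.col is the fast path; it requires
# finite entries, so -Inf is floored first).
#' @noRd
row_logsumexp <- function(X) {
  Xf <- pmax(X, -.Machine$double.xmax)
  m <- Xf[cbind(seq_len(nrow(X)), max.col(Xf, ties.method = "first"))]
  m + log(rowSums(exp(X - m)))
}

# Column-wise log-sum-exp of a matrix.
#' @noRd
col_logsumexp <- function(X) {
  row_logsumexp(t(X))
}

#' @noRd
symmetrize <- function(B) (B + t(B)) / 2

# Clamp eigenvalues of a symmetric matrix to at least `floor`; returns the
# repaired matrix and whether clamping was needed.
#' @noRd
spd_floor <- function(B, floor = 1e-8) {
  B <- symmetrize(B)
  # Fast path: a successful Cholesky proves positive-definiteness.
  ok <- tryCatch({ chol(B); TRUE }, error = function(e) FALSE)
  if (ok) return(list(B = B, repaired = FALSE))
  e <- eigen(B, symmetric = TRUE)
  v <- pmax(e$values, floor)
  list(B = symmetrize(e$vectors %*% (v * t(e$vectors))), repaired = TRUE)
}

#' @noRd
check_spd <- function(S, name = "matrix", tol = 1e-10) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop(name, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S)))) {
    stop(name, " is not symmetric", call. = FALSE)
  }
  ev <- eigen(symmetrize(S), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(name, " is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  invisible(TRUE)
}

# Multivariate log-gamma and digamma, dimension M.
#' @noRd
lmvgamma <- function(a, M) {
  (M * (M - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(M)) / 2))
}

#' @noRd
mvdigamma <- function(a, M) sum(digamma(a + (1 - seq_len(M)) / 2))

# log-determinant of an SPD matrix via Cholesky.
#' @noRd
logdet_spd <- function(B) 2 * sum(log(diag(chol(B))))

# Draw n samples from N(0, Sigma) using the current RNG stream.
#' @noRd
rmvn0 <- function(n, Sigma) {
  M <- nrow(Sigma)
  Z <- matrix(stats::rnorm(n * M), n, M)
  Z %*% chol(Sigma)
}

# Covariance matrix with unit diagonal and correlation r inside each index
# block, zero elsewhere.
#' @noRd
block_correlation <- function(M, blocks, r) {
  S <- diag(M)
  for (idx in blocks) S[idx, idx] <- r
  diag(S) <- 1
  check_spd(S, "block correlation matrix")
  S
}
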