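#' Expected covariance matrix of a state
#'
#' Under the Normal-Wishart posterior the state precision follows a Wishart
#' distribution and the expected covariance is `scale_matrix / dof`
#' (`b_k / a_k`). The Bayesian update regularizes the scale matrix, so the
#' result is always full rank and can be inverted for partial correlations.
#'
#' @param post a `vbhmm_posterior` from [fit_vbhmm()] (or any object with a
#'   `nw` list of Normal-Wishart parameter sets).
#' @param k state index in `1..K`.
#' @return `M x M` symmetric positive-definite matrix.
#' @export
expected_covariance <- function(post, k) {
  K <- length(post$nw)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > K || k != round(k)) {
    stop("state index k must be an integer in 1..", K, call. = FALSE)
  }
  nw <- post$nw[[k]]
  symmetrize(nw$B / nw$a)
}

# E[log x] under Dirichlet(alpha).
#' @noRd
dirichlet_elog <- function(alpha) {
  check_concentrations(alpha)
  digamma(alpha) - digamma(sum(alpha))
}

# E[log det Lambda] for Lambda ~ Wishart with dof a and inverse scale B
# (i.e. E[Lambda] = a * B^{-1}).
#' @noRd
nw_elogdet_precision <- function(a, B) {
  M <- nrow(B)
  mvdigamma(a / 2, M) + M * log(2) - logdet_spd(B)
}

#' Variational expectations of the HMM parameters
#'
#' Returns the quantities the VB E-step and Viterbi decoding operate on:
#' `E[log pi]`, `E[log A]` (elementwise digamma differences of the Dirichlet
#' posteriors) and a function evaluating, for a block of observations, the
#' expected Gaussian log-density under each state's Normal-Wishart
#' posterior,
#' \deqn{E[\log N(y | \mu_k, \Lambda_k^{-1})] =
#'   \tfrac12 E[\log\det\Lambda_k] - \tfrac{M}{2}\log 2\pi
#'   - \tfrac12\left(M/\lambda_k + a_k (y-m_k)^\top B_k^{-1} (y-m_k)\right).}
#' Note `exp(E[log A])` rows are sub-normalized (sum to at most 1, by
#' Jensen's inequality); this is the quantity the VB forward-backward
#' recursion requires, not a posterior-mean transition matrix.
#'
#' @param post a `vbhmm_posterior` (or priors object with the same fields).
#' @return list with `log_pi` (length `K`), `log_A` (`K x K`) and
#'   `emission_loglik`, a function mapping a `T x M` matrix to the `T x K`
#'   matrix of expected log-densities.
#' @export
expected_log_params <- function(post) {
  K <- length(post$nw)
  log_pi <- dirichlet_elog(post$pi)
  log_A <- t(apply(post$A, 1L, dirichlet_elog))
  if (K == 1) log_A <- matrix(log_A, 1, 1)
  M <- length(post$nw[[1]]$m)
  # Pre-factor each state's scale matrix once.
  means <- vapply(post$nw, function(nw) nw$m, numeric(M))
  if (M == 1) means <- matrix(means, 1, K)
  rinv <- do.call(cbind, lapply(post$nw, function(nw) {
    backsolve(chol(nw$B), diag(M))
  }))
  consts <- vapply(post$nw, function(nw) {
    0.5 * nw_elogdet_precision(nw$a, nw$B) -
      0.5 * M * log(2 * pi) - 0.5 * M / nw$lambda
  }, numeric(1))
  dofs <- vapply(post$nw, function(nw) nw$a, numeric(1))
  emission_loglik <- function(Y) {
    # Mahalanobis distances under B^{-1} via the Cholesky inverses (C++).
    out <- .emission_cpp(as.matrix(Y), means, rinv, consts, dofs)
    if (any(!is.finite(out))) {
      bad <- which(!is.finite(out), arr.ind = TRUE)[1, ]
      stop("non-finite emission term at time ", bad[1], ", state ", bad[2],
           call. = FALSE)
    }
    out
  }
  list(log_pi = log_pi, log_A = log_A, emission_loglik = emission_loglik)
}
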