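#' Conjugate priors for the variational Bayes HMM
#'
#' Builds the Dirichlet priors on the initial distribution and on each row
#' of the transition matrix, and the Normal-Wishart priors on each state's
#' Gaussian mean and precision. The Dirichlet concentrations default to
#' `1/K`, a sparsity-inducing choice under which states unsupported by the
#' data are pruned (they end with zero Viterbi occupancy). The Wishart scale
#' matrix defaults to `nw_dof * diag(v)` with `v` the per-node variance
#' pooled over all subjects, so the prior expected covariance
#' (`scale_matrix / dof`) matches the data scale.
#'
#' With `fix_means = TRUE` (the resting-state default) the Normal scale
#' hyperparameter is set to `lambda = 1000`, which pins every state's
#' posterior mean at the prior mean (zero): states then differ only through
#' their covariance structure. With `fix_means = FALSE` a non-informative
#' `lambda = 0.001` lets the data move the means, appropriate for task-like
#' data with level shifts.
#'
#' @param data a [roi_ts_set] (used for `M` and the empirical node
#'   variances), or `NULL` if both `M` and `nw_scale` are supplied.
#' @param K initial number of states (default 25; surplus states are pruned
#'   during fitting).
#' @param fix_means logical; see Details.
#' @param dirichlet_concentration concentration for the initial-distribution
#'   prior and each transition-row prior (default `1/K`).
#' @param nw_dof Wishart degrees of freedom (default `M + 2`; must exceed
#'   `M - 1`).
#' @param nw_scale optional `M x M` SPD Wishart scale matrix; default
#'   `nw_dof * diag(pooled node variances)`.
#' @param nw_mean optional prior mean vector (default zero).
#' @param M node count, required when `data` is `NULL`.
#'
#' @return An object of class `vbhmm_priors`: list with `K`, `M`, `pi`
#'   (length-`K` concentrations), `A` (`K x K`; row `j` holds the
#'   concentrations of transition row `j`), `nw` (list of `K` lists with
#'   `m`, `lambda`, `a`, `B`) and `fix_means`.
#' @export
vbhmm_priors <- function(data = NULL, K = 25, fix_means = TRUE,
                         dirichlet_concentration = 1 / K,
                         nw_dof = NULL, nw_scale = NULL, nw_mean = NULL,
                         M = NULL) {
  if (!is.null(data)) {
    stopifnot(inherits(data, "roi_ts_set"))
    M <- data$M
  }
  if (is.null(M)) stop("supply `data` or `M`", call. = FALSE)
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (dirichlet_concentration <= 0) {
    stop("dirichlet_concentration must be > 0", call. = FALSE)
  }
  if (is.null(nw_dof)) nw_dof <- M + 2
  if (nw_dof <= M - 1) stop("nw_dof must exceed M - 1", call. = FALSE)
  if (is.null(nw_scale)) {
    if (is.null(data)) {
      stop("supply `nw_scale` when `data` is NULL", call. = FALSE)
    }
    v <- apply(stack_series(data), 2L, stats::var)
    nw_scale <- nw_dof * diag(v, M)
  }
  check_spd(nw_scale, "nw_scale")
  if (is.null(nw_mean)) nw_mean <- rep(0, M)
  stopifnot(length(nw_mean) == M)
  lambda <- if (fix_means) 1000 else 0.001
  nw <- replicate(K, list(m = nw_mean, lambda = lambda, a = nw_dof,
                          B = symmetrize(nw_scale)),
                  simplify = FALSE)
  structure(
    list(K = K, M = M,
         pi = rep(dirichlet_concentration, K),
         A = matrix(dirichlet_concentration, K, K),
         nw = nw, fix_means = fix_means),
    class = "vbhmm_priors"
  )
}

#' @export
print.vbhmm_priors <- function(x, ...) {
  cat("VB-HMM priors: K = ", x$K, ", M = ", x$M,
      ", Dirichlet concentration = ", format(x$pi[1]),
      ", lambda = ", format(x$nw[[1]]$lambda),
      if (x$fix_means) " (means fixed at prior)" else "", "\n", sep = "")
  invisible(x)
}

#' @noRd
check_concentrations <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("Dirichlet concentrations must be strictly positive", call. = FALSE)
  }
  invisible(TRUE)
}
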