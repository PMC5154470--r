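#' K-means initialization of the state responsibilities
#'
#' Pools all subjects' samples, clusters them into `K` groups with
#' [stats::kmeans()], and returns one-hot responsibility matrices per
#' subject. Clusters that end up empty simply seed states that the sparse
#' priors will prune during fitting.
#'
#' @param data a [roi_ts_set].
#' @param K number of clusters/states.
#' @param seed integer seed making the clustering reproducible.
#' @return named list (per subject) of `T_s x K` one-hot matrices.
#' @export
kmeans_initialize <- function(data, K, seed) {
  stopifnot(inherits(data, "roi_ts_set"))
  Y <- stack_series(data)
  if (nrow(Y) < K) {
    stop("total sample count (", nrow(Y), ") is smaller than K = ", K,
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  km <- NULL
  for (attempt in 0:4) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(Y, centers = K, nstart = 1,
                                     iter.max = 100)),
      error = function(e) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km)) stop("k-means initialization failed", call. = FALSE)
  assign <- km$cluster
  Ts <- vapply(data$subjects, nrow, integer(1))
  ends <- cumsum(Ts)
  starts <- ends - Ts + 1
  out <- vector("list", length(Ts))
  for (s in seq_along(Ts)) {
    z <- assign[starts[s]:ends[s]]
    G <- matrix(0, Ts[s], K)
    G[cbind(seq_len(Ts[s]), z)] <- 1
    out[[s]] <- G
  }
  names(out) <- names(data$subjects)
  out
}

# Pairwise "counts" implied by hard assignments: outer products of
# consecutive one-hot rows. Used to seed the first M-step.
#' @noRd
onehot_pairwise <- function(gamma_list) {
  lapply(gamma_list, function(G) {
    Tn <- nrow(G); K <- ncol(G)
    xi <- array(0, dim = c(Tn - 1L, K, K))
    for (t in seq_len(Tn - 1L)) xi[t, , ] <- tcrossprod(G[t, ], G[t + 1L, ])
    xi
  })
}

#' Variational E-step (forward-backward)
#'
#' Runs the forward-backward recursion per subject in log space over
#' `exp(E[log pi])`, `exp(E[log A])` and the expected emission
#' log-densities, returning the singleton state marginals, the pairwise
#' (consecutive-time) joint marginals, and the per-subject log normalizer.
#' Working in log space with log-sum-exp makes underflow impossible.
#'
#' @param post a `vbhmm_posterior` (current variational parameters).
#' @param data a [roi_ts_set].
#' @return list with `gamma` (per subject `T_s x K`), `xi` (per subject
#'   `(T_s-1) x K x K`) and `logZ` (numeric vector per subject).
#' @export
e_step <- function(post, data) {
  stopifnot(inherits(data, "roi_ts_set"))
  ep <- expected_log_params(post)
  K <- length(ep$log_pi)
  gamma <- xi <- vector("list", length(data$subjects))
  logZ <- numeric(length(data$subjects))
  for (s in seq_along(data$subjects)) {
    lrho <- ep$emission_loglik(data$subjects[[s]])
    fb <- forward_backward(ep$log_pi, ep$log_A, lrho, full_xi = TRUE)
    gamma[[s]] <- fb$gamma
    xi[[s]] <- fb$xi
    logZ[s] <- fb$logZ
  }
  names(gamma) <- names(xi) <- names(logZ) <- names(data$subjects)
  list(gamma = gamma, xi = xi, logZ = logZ)
}

# Log-space forward-backward for one subject (compiled fast path).
#' @noRd
forward_backward <- function(log_pi, log_A, lrho, full_xi = TRUE) {
  out <- .fb_cpp(log_pi, log_A, lrho, full_xi)
  names(out$logZ) <- NULL
  out
}

# Pure-R reference implementation of the same recursion (kept for
# cross-checking the compiled path in the test suite).
#' @noRd
forward_backward_r <- function(log_pi, log_A, lrho) {
  Tn <- nrow(lrho); K <- ncol(lrho)
  la <- matrix(0, Tn, K)  # log forward messages
  lb <- matrix(0, Tn, K)  # log backward messages
  la[1, ] <- log_pi + lrho[1, ]
  tlog_A <- t(log_A)
  if (Tn > 1) {
    for (t in 2:Tn) {
      # la[t,k] = lrho[t,k] + LSE_j(la[t-1,j] + log_A[j,k])
      la[t, ] <- lrho[t, ] + row_logsumexp(tlog_A + rep(la[t - 1, ], each = K))
    }
    for (t in (Tn - 1):1) {
      v <- lrho[t + 1, ] + lb[t + 1, ]
      lb[t, ] <- row_logsumexp(log_A + rep(v, each = K))
    }
  }
  logZ <- logsumexp(la[Tn, ])
  lg <- la + lb - logZ
  gamma <- exp(lg)
  gamma <- gamma / rowSums(gamma)
  xi <- array(0, dim = c(max(Tn - 1L, 0L), K, K))
  if (Tn > 1) {
    # lx[t,j,k] = la[t,j] + log_A[j,k] + lrho[t+1,k] + lb[t+1,k] - logZ,
    # built in one shot via column-major replication.
    v <- (lrho + lb)[-1, , drop = FALSE]
    lx <- array(la[-Tn, , drop = FALSE], dim = c(Tn - 1L, K, K)) +
      array(v[, rep(seq_len(K), each = K), drop = FALSE],
            dim = c(Tn - 1L, K, K)) +
      array(rep(log_A, each = Tn - 1L), dim = c(Tn - 1L, K, K)) - logZ
    xi <- exp(lx)
    dim(xi) <- c(Tn - 1L, K * K)
    xi <- xi / rowSums(xi)
    dim(xi) <- c(Tn - 1L, K, K)
  }
  list(gamma = gamma, xi = xi, logZ = logZ)
}

#' Variational M-step (conjugate hyperparameter updates)
#'
#' Standard conjugate updates: the Dirichlet posteriors add the expected
#' counts to the prior concentrations (initial-state responsibilities for
#' `pi`, summed pairwise marginals for each transition row), and each
#' state's Normal-Wishart posterior absorbs the responsibility-weighted
#' sample moments:
#' \deqn{\lambda_k' = \lambda_0 + N_k,\quad
#'   m_k' = (\lambda_0 m_0 + N_k \bar y_k)/\lambda_k',\quad
#'   a_k' = a_0 + N_k,}
#' \deqn{B_k' = B_0 + S_k +
#'   \frac{\lambda_0 N_k}{\lambda_0 + N_k}(\bar y_k - m_0)(\bar y_k - m_0)^\top}
#' with `N_k` the total responsibility, `ybar_k` the weighted mean and `S_k`
#' the weighted scatter about `ybar_k`. With mean-fixing priors
#' (`lambda_0 = 1000`) the posterior means stay pinned near the prior mean,
#' so states are distinguished by covariance alone. A state receiving no
#' responsibility keeps its prior exactly. Scale matrices are symmetrized
#' after the update and their eigenvalues floored at `1e-8` (a warning is
#' emitted if the floor ever binds).
#'
#' @param gamma per-subject list of `T_s x K` responsibility matrices.
#' @param xi per-subject list of `(T_s-1) x K x K` pairwise marginals.
#' @param data a [roi_ts_set].
#' @param priors a [vbhmm_priors] object.
#' @return a `vbhmm_posterior` holding the updated hyperparameters
#'   (responsibilities and traces are attached by [fit_vbhmm()]).
#' @export
m_step <- function(gamma, xi, data, priors) {
  stopifnot(inherits(data, "roi_ts_set"), inherits(priors, "vbhmm_priors"))
  K <- priors$K; M <- priors$M
  S <- length(data$subjects)
  if (length(gamma) != S || length(xi) != S) {
    stop("gamma/xi must have one element per subject", call. = FALSE)
  }
  for (s in seq_len(S)) {
    if (!is.matrix(gamma[[s]]) || ncol(gamma[[s]]) != K ||
        nrow(gamma[[s]]) != nrow(data$subjects[[s]])) {
      stop("gamma[[", s, "]] has the wrong shape", call. = FALSE)
    }
  }
  pi_counts <- Reduce(`+`, lapply(gamma, function(G) G[1, ]))
  trans_counts <- Reduce(`+`, lapply(xi, function(x) colSums(x, dims = 1L)))
  Yall <- stack_series(data)
  Gall <- do.call(rbind, gamma)
  m_step_core(pi_counts, trans_counts, Gall, Yall, priors)
}

# Conjugate updates from sufficient statistics (shared by m_step and the
# fit loop, which precomputes the stacked data once).
#' @noRd
m_step_core <- function(pi_counts, trans_counts, Gall, Yall, priors) {
  K <- priors$K; M <- priors$M
  pi_post <- priors$pi + pi_counts
  A_post <- priors$A + trans_counts
  Nk <- colSums(Gall)
  nw_post <- vector("list", K)
  repaired <- FALSE
  for (k in seq_len(K)) {
    p <- priors$nw[[k]]
    n <- Nk[k]
    if (n <= 0) {
      nw_post[[k]] <- p
      next
    }
    w <- Gall[, k]
    ybar <- colSums(Yall * w) / n
    D <- Yall - rep(ybar, each = nrow(Yall))
    Sk <- crossprod(D * w, D)
    d0 <- ybar - p$m
    B <- p$B + Sk + (p$lambda * n / (p$lambda + n)) * tcrossprod(d0)
    fix <- spd_floor(B)
    if (fix$repaired) repaired <- TRUE
    nw_post[[k]] <- list(
      m = (p$lambda * p$m + n * ybar) / (p$lambda + n),
      lambda = p$lambda + n,
      a = p$a + n,
      B = fix$B
    )
  }
  if (repaired) {
    warning("a posterior scale matrix lost positive-definiteness; ",
            "eigenvalues floored at 1e-8", call. = FALSE)
  }
  structure(
    list(K = K, M = M, pi = pi_post, A = A_post, nw = nw_post,
         priors = priors),
    class = "vbhmm_posterior"
  )
}

# KL(Dir(aq) || Dir(ap)) in closed form.
#' @noRd
kl_dirichlet <- function(aq, ap) {
  check_concentrations(aq); check_concentrations(ap)
  lgamma(sum(aq)) - sum(lgamma(aq)) - lgamma(sum(ap)) + sum(lgamma(ap)) +
    sum((aq - ap) * (digamma(aq) - digamma(sum(aq))))
}

# KL between Normal-Wishart distributions q=(m1,l1,a1,B1), p=(m0,l0,a0,B0),
# where the precision ~ Wishart with E[Lambda] = a * B^{-1}.
#' @noRd
kl_normal_wishart <- function(q, p) {
  M <- length(q$m)
  Rq <- chol(q$B)
  Binv_q <- chol2inv(Rq)
  # Conditional Gaussian part, averaged over q(Lambda).
  dm <- q$m - p$m
  kl_norm <- 0.5 * (M * p$lambda / q$lambda - M + M * log(q$lambda / p$lambda) +
                      p$lambda * q$a * drop(t(dm) %*% Binv_q %*% dm))
  # Wishart part: scales V = B^{-1}.
  ldq <- -2 * sum(log(diag(Rq)))
  ldp <- -logdet_spd(p$B)
  kl_wish <- -(p$a / 2) * (ldq - ldp) +
    (q$a / 2) * (sum(p$B * Binv_q) - M) +
    lmvgamma(p$a / 2, M) - lmvgamma(q$a / 2, M) +
    ((q$a - p$a) / 2) * mvdigamma(q$a / 2, M)
  kl_norm + kl_wish
}

#' @noRd
kl_total <- function(post, priors) {
  kl <- kl_dirichlet(post$pi, priors$pi)
  for (j in seq_len(priors$K)) kl <- kl + kl_dirichlet(post$A[j, ], priors$A[j, ])
  for (k in seq_len(priors$K)) {
    kl <- kl + kl_normal_wishart(post$nw[[k]], priors$nw[[k]])
  }
  kl
}

#' Negative free energy (evidence lower bound)
#'
#' Computes `F(q) = sum_s log Z_s - KL(q(pi)||p(pi)) - sum_j
#' KL(q(A_j)||p(A_j)) - sum_k KL(q(NW_k)||p(NW_k))`, where `log Z_s` is the
#' forward-recursion normalizer of subject `s` under the sub-normalized
#' expected parameters. This equals the mean-field evidence lower bound when
#' the state posterior `q(Z)` is the one induced by the current parameter
#' posterior (i.e. immediately after an E-step), and it is the quantity
#' [fit_vbhmm()] monitors for convergence: it is non-decreasing over the
#' coordinate-ascent iterations.
#'
#' With a posterior equal to the priors and no data, all terms vanish and
#' `F = 0`.
#'
#' @param post a `vbhmm_posterior`.
#' @param priors the [vbhmm_priors] the model was fit with.
#' @param data a [roi_ts_set]; may contain zero subjects, in which case only
#'   the (negated) KL terms are returned.
#' @return scalar negative free energy.
#' @export
free_energy <- function(post, priors, data = NULL) {
  lz <- 0
  if (!is.null(data) && length(data$subjects) > 0) {
    lz <- sum(e_step(post, data)$logZ)
  }
  lz - kl_total(post, priors)
}

#' Fit a variational Bayes hidden Markov model
#'
#' For each random restart: initialize hard responsibilities by K-means,
#' then alternate the conjugate M-step and the forward-backward E-step until
#' the negative free energy improves by less than `tol` (absolute change in
#' nats per iteration, the convention of the standard variational-inference
#' libraries) or `max_iterations` is reached. Fully converging each restart
#' matters beyond accuracy: the automatic merging of redundant states
#' happens late in the ascent, and the across-restart model selection
#' compares final bounds, so stopping early both inflates the state count
#' and corrupts the restart choice. The restart with the highest final `F`
#' is returned. Restart `r` uses seed `seed + r - 1`, so results are exactly
#' reproducible. Initialized with more states than the data support, the
#' sparse Dirichlet priors leave surplus states without responsibility;
#' those states retain (approximately) their priors and never appear in the
#' Viterbi decoding.
#'
#' @param data a [roi_ts_set].
#' @param priors optional [vbhmm_priors]; built with defaults (and the given
#'   `K`) when `NULL`.
#' @param K initial number of states (ignored if `priors` is supplied).
#' @param n_restarts number of random K-means restarts (default 100).
#' @param tol convergence tolerance on the per-iteration free-energy
#'   improvement, in nats (default `1e-3`).
#' @param max_iterations cap on M/E cycles per restart (default 200).
#' @param seed integer seed.
#' @param verbose print one line per restart.
#'
#' @return A `vbhmm_posterior`: hyperparameters (`pi`, `A`, `nw`), the
#'   per-subject `responsibilities` and `pairwise` marginals, the
#'   `free_energy_trace` of the winning restart, `converged`,
#'   `n_iterations`, `winning_restart`, `logZ`, and the `priors` used. If no
#'   restart converged the best run so far is returned with
#'   `converged = FALSE` and a warning.
#' @export
fit_vbhmm <- function(data, priors = NULL, K = 25, n_restarts = 100,
                      tol = 1e-3, max_iterations = 200, seed = 1,
                      verbose = FALSE) {
  stopifnot(inherits(data, "roi_ts_set"))
  if (is.null(priors)) priors <- vbhmm_priors(data, K = K)
  K <- priors$K
  if (n_restarts < 1) stop("n_restarts must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  # Stack the data once; the per-iteration loop works on sufficient
  # statistics and defers the full pairwise-marginal arrays to a single
  # final E-step.
  Yall <- stack_series(data)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    gamma <- kmeans_initialize(data, K, seed = as.integer(seed) + r - 1L)
    pi_counts <- Reduce(`+`, lapply(gamma, function(G) G[1, ]))
    trans_counts <- Reduce(`+`, lapply(onehot_pairwise(gamma),
                                       function(x) colSums(x, dims = 1L)))
    trace <- numeric(0)
    converged <- FALSE
    post <- NULL
    F_prev <- NA_real_
    for (it in seq_len(max_iterations)) {
      post <- m_step_core(pi_counts, trans_counts, do.call(rbind, gamma),
                          Yall, priors)
      ep <- expected_log_params(post)
      logZ <- numeric(length(data$subjects))
      pi_counts <- 0
      trans_counts <- 0
      for (s in seq_along(data$subjects)) {
        fb <- forward_backward(ep$log_pi, ep$log_A,
                               ep$emission_loglik(data$subjects[[s]]),
                               full_xi = FALSE)
        gamma[[s]] <- fb$gamma
        pi_counts <- pi_counts + fb$gamma[1, ]
        trans_counts <- trans_counts + fb$xi_sum
        logZ[s] <- fb$logZ
      }
      F_cur <- sum(logZ) - kl_total(post, priors)
      trace <- c(trace, F_cur)
      if (!is.na(F_prev) && abs(F_cur - F_prev) < tol) {
        converged <- TRUE
        break
      }
      F_prev <- F_cur
    }
    F_final <- trace[length(trace)]
    if (verbose) {
      message(sprintf("restart %d: F = %.4f after %d iteration(s)%s",
                      r, F_final, length(trace),
                      if (converged) "" else " (not converged)"))
    }
    if (is.null(best) || F_final > best$F) {
      best <- list(post = post, trace = trace,
                   converged = converged, F = F_final, restart = r)
    }
  }
  if (!best$converged) {
    warning("no restart converged within max_iterations; ",
            "returning the best run so far", call. = FALSE)
  }
  out <- best$post
  # Recompute the final state posterior (with full pairwise marginals)
  # under the winning hyperparameters.
  es <- e_step(out, data)
  out$responsibilities <- es$gamma
  out$pairwise <- es$xi
  out$free_energy_trace <- best$trace
  out$converged <- best$converged
  out$n_iterations <- length(best$trace)
  out$winning_restart <- best$restart
  out$logZ <- es$logZ
  out$seed <- as.integer(seed)
  out
}

#' @export
print.vbhmm_posterior <- function(x, ...) {
  cat("VB-HMM posterior: K = ", x$K, ", M = ", x$M, sep = "")
  if (!is.null(x$free_energy_trace)) {
    cat(", F = ", format(x$free_energy_trace[length(x$free_energy_trace)]),
        " after ", x$n_iterations, " iteration(s)",
        if (isTRUE(x$converged)) " (converged)" else " (not converged)",
        ", winning restart ", x$winning_restart, sep = "")
  }
  cat("\n")
  invisible(x)
}
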