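# Shared fixtures and independent oracles used across the test files.

# --- fixtures -------------------------------------------------------------

# A bare posterior/parameter object with given Dirichlet and Normal-Wishart
# hyperparameters, suitable for expected_log_params()/e_step()/viterbi().
make_posterior <- function(alpha_pi, alpha_A, nw) {
  structure(list(K = length(alpha_pi), M = length(nw[[1]]$m),
                 pi = alpha_pi, A = alpha_A, nw = nw),
            class = "vbhmm_posterior")
}

# Normal-Wishart parameter set whose expected covariance is (approximately)
# `Sigma` and whose mean is sharply `m` (large lambda and dof make the
# expected emission density close to the plain Gaussian N(m, Sigma)).
sharp_nw <- function(m, Sigma, a = 1e6) {
  list(m = m, lambda = 1e6, a = a, B = a * Sigma)
}

# Dirichlet concentrations so large that exp(E[log .]) is numerically equal
# to the normalized probabilities `p`.
sharp_dirichlet <- function(p, c = 1e9) c * p

# A small two-state posterior over M = 2 nodes with distinct means.
two_state_posterior <- function(pi = c(0.5, 0.5),
                                A = matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
                                           byrow = TRUE),
                                m1 = c(0, 0), m2 = c(3, 3)) {
  make_posterior(sharp_dirichlet(pi),
                 rbind(sharp_dirichlet(A[1, ]), sharp_dirichlet(A[2, ])),
                 list(sharp_nw(m1, diag(2)), sharp_nw(m2, diag(2))))
}

# --- brute-force HMM path enumeration oracle ------------------------------

# Enumerate all K^T paths under the given expected log-parameters and
# emission log-densities; returns exact gamma, xi, logZ and the max-weight
# path. Independent of the forward-backward recursion.
enumerate_hmm <- function(log_pi, log_A, lrho) {
  Tn <- nrow(lrho); K <- ncol(lrho)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  logw <- apply(paths, 1L, function(z) {
    lw <- log_pi[z[1]] + lrho[1, z[1]]
    if (Tn > 1) {
      for (t in 2:Tn) lw <- lw + log_A[z[t - 1], z[t]] + lrho[t, z[t]]
    }
    lw
  })
  m <- max(logw)
  w <- exp(logw - m)
  Z <- sum(w)
  gamma <- matrix(0, Tn, K)
  for (t in seq_len(Tn)) {
    for (k in seq_len(K)) gamma[t, k] <- sum(w[paths[, t] == k]) / Z
  }
  xi <- array(0, dim = c(max(Tn - 1, 0), K, K))
  if (Tn > 1) {
    for (t in seq_len(Tn - 1)) {
      for (j in seq_len(K)) for (k in seq_len(K)) {
        xi[t, j, k] <- sum(w[paths[, t] == j & paths[, t + 1] == k]) / Z
      }
    }
  }
  list(gamma = gamma, xi = xi, logZ = m + log(Z),
       map_path = paths[which.max(logw), ])
}

# --- set-partition enumeration oracle for community detection -------------

# All set partitions of n elements as canonical label vectors (restricted
# growth strings). Bell(6) = 203, small enough for exhaustive search.
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, next_max) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (g in seq_len(next_max)) {
      grow(c(labels, g), max(next_max, g + 1L))
    }
  }
  grow(integer(0), 1L)
  out
}

# Signed modularity of a partition, computed from first principles with the
# asymmetric negative-weight convention (positive part normalized by total
# positive strength, negative part by total strength).
signed_modularity_oracle <- function(W, p, gamma = 1) {
  W <- (W + t(W)) / 2
  diag(W) <- 0
  Wp <- pmax(W, 0); Wn <- -pmin(W, 0)
  sp <- sum(Wp); sn <- sum(Wn)
  same <- outer(p, p, "==")
  q <- 0
  if (sp > 0) {
    q <- q + (sum(Wp[same]) - gamma * sum(tcrossprod(rowSums(Wp))[same]) / sp) / sp
  }
  if (sn > 0) {
    q <- q - (sum(Wn[same]) - gamma * sum(tcrossprod(rowSums(Wn))[same]) / sn) / (sp + sn)
  }
  q
}

# Best partition by exhaustive search, excluding the constant diagonal term
# exactly as detect_communities reports modularity.
best_partition_oracle <- function(W, gamma = 1) {
  parts <- all_partitions(nrow(W))
  qs <- vapply(parts, function(p) {
    signed_modularity_oracle(W, p, gamma) - diag_modularity(W, gamma)
  }, numeric(1))
  list(partition = parts[[which.max(qs)]], modularity = max(qs))
}

# Constant diagonal contribution of the modularity matrix.
diag_modularity <- function(W, gamma = 1) {
  W <- (W + t(W)) / 2
  diag(W) <- 0
  Wp <- pmax(W, 0); Wn <- -pmin(W, 0)
  sp <- sum(Wp); sn <- sum(Wn)
  d <- 0
  if (sp > 0) d <- d + sum(diag(-gamma * tcrossprod(rowSums(Wp)) / sp)) / sp
  if (sn > 0) d <- d - sum(diag(-gamma * tcrossprod(rowSums(Wn)) / sn)) / (sp + sn)
  d
}

# --- misc -----------------------------------------------------------------

# Two-block signed weight matrix: `within` inside each half, `between`
# across halves.
planted_signed_blocks <- function(n = 6, within = 0.8, between = -0.2) {
  half <- n %/% 2
  W <- matrix(between, n, n)
  W[seq_len(half), seq_len(half)] <- within
  W[(half + 1):n, (half + 1):n] <- within
  diag(W) <- 0
  W
}

expect_partitions_equal <- function(p1, p2) {
  expect_true(partitions_equal(p1, p2),
              label = sprintf("partition (%s) == (%s)",
                              paste(p1, collapse = ","),
                              paste(p2, collapse = ",")))
}
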