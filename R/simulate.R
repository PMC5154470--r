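#' Simulate block-design correlation switching (two nodes)
#'
#' Generates zero-mean bivariate Gaussian series whose correlation switches
#' with a block design: in the "OFF" state (state 1) the two nodes are
#' negatively correlated, in the "ON" state (state 2) they are uncorrelated.
#' Blocks alternate OFF, ON, OFF, ... with a fixed block length.
#'
#' @param n_subjects number of simulated subjects (default 5).
#' @param T_total series length per subject (default 240).
#' @param block_length samples per block (default 30).
#' @param corr_off correlation in the OFF state (default -0.8; must have
#'   absolute value < 1).
#' @param corr_on correlation in the ON state (default 0).
#' @param tr_seconds sampling interval attached to the data (default 0.72).
#' @param seed integer seed.
#' @return list with `data` (a [roi_ts_set]), `labels` (per-subject integer
#'   vectors of true states) and `state_covariances`.
#' @export
simulate_block_design <- function(n_subjects = 5, T_total = 240,
                                  block_length = 30, corr_off = -0.8,
                                  corr_on = 0, tr_seconds = 0.72, seed = 1) {
  if (abs(corr_off) >= 1 || abs(corr_on) >= 1) {
    stop("|correlation| must be < 1", call. = FALSE)
  }
  covs <- list(
    matrix(c(1, corr_off, corr_off, 1), 2, 2),
    matrix(c(1, corr_on, corr_on, 1), 2, 2)
  )
  n_blocks <- ceiling(T_total / block_length)
  labels1 <- rep(rep(c(1L, 2L), length.out = n_blocks), each = block_length)
  labels1 <- labels1[seq_len(T_total)]
  set.seed(as.integer(seed))
  series <- vector("list", n_subjects)
  labels <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    labels[[s]] <- labels1
    Y <- matrix(0, T_total, 2)
    for (k in 1:2) {
      idx <- which(labels1 == k)
      if (length(idx)) Y[idx, ] <- rmvn0(length(idx), covs[[k]])
    }
    series[[s]] <- Y
  }
  data <- roi_ts_set(series, tr_seconds)
  names(labels) <- names(data$subjects)
  list(data = data, labels = labels, state_covariances = covs)
}

#' Simulate an HMM with state-specific covariances
#'
#' Samples hidden state sequences from a Markov chain (uniform initial
#' distribution unless given) and draws zero-mean multivariate Gaussian
#' observations with a state-specific covariance. Defaults: 6 nodes, 2
#' states with a near-diagonal transition matrix, state 1 correlating nodes
#' 1-3 (r = 0.8) and state 2 correlating nodes 4-6.
#'
#' @param n_subjects number of subjects (default 5).
#' @param T_total series length per subject (default 232).
#' @param transition row-stochastic `K x K` matrix (default
#'   `[[0.98, 0.02], [0.02, 0.98]]`).
#' @param state_covariances list of SPD matrices, one per state.
#' @param init initial state distribution (default uniform).
#' @param tr_seconds sampling interval (default 0.72).
#' @param seed integer seed.
#' @return list with `data`, `labels`, `state_covariances` and `transition`.
#' @export
simulate_hmm <- function(n_subjects = 5, T_total = 232,
                         transition = matrix(c(0.98, 0.02, 0.02, 0.98), 2, 2,
                                             byrow = TRUE),
                         state_covariances = list(
                           block_correlation(6, list(1:3), 0.8),
                           block_correlation(6, list(4:6), 0.8)),
                         init = NULL, tr_seconds = 0.72, seed = 1) {
  K <- nrow(transition)
  if (ncol(transition) != K || any(transition < 0) ||
      max(abs(rowSums(transition) - 1)) > 1e-12) {
    stop("`transition` must be a row-stochastic square matrix", call. = FALSE)
  }
  if (length(state_covariances) != K) {
    stop("need one covariance per state", call. = FALSE)
  }
  for (S in state_covariances) check_spd(S, "state covariance")
  M <- nrow(state_covariances[[1]])
  if (is.null(init)) init <- rep(1 / K, K)
  set.seed(as.integer(seed))
  series <- labels <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    z <- integer(T_total)
    z[1] <- sample.int(K, 1, prob = init)
    for (t in 2:T_total) z[t] <- sample.int(K, 1, prob = transition[z[t - 1], ])
    Y <- matrix(0, T_total, M)
    for (k in seq_len(K)) {
      idx <- which(z == k)
      if (length(idx)) Y[idx, ] <- rmvn0(length(idx), state_covariances[[k]])
    }
    series[[s]] <- Y
    labels[[s]] <- z
  }
  data <- roi_ts_set(series, tr_seconds)
  names(labels) <- names(data$subjects)
  list(data = data, labels = labels, state_covariances = state_covariances,
       transition = transition)
}

#' Simulate split-half correlation states (six nodes)
#'
#' In the first half of each series nodes 1-3 are mutually correlated
#' (nodes 4-6 independent); in the second half the roles swap. Labels are
#' state 1 for the first half, state 2 for the second.
#'
#' @param n_subjects number of subjects (default 5).
#' @param T_total total series length; must be even (default 232, i.e.
#'   116 + 116).
#' @param r within-block correlation (default 0.8).
#' @param tr_seconds sampling interval (default 0.72).
#' @param seed integer seed.
#' @return list with `data`, `labels` and `state_covariances`.
#' @export
simulate_split_half <- function(n_subjects = 5, T_total = 232, r = 0.8,
                                tr_seconds = 0.72, seed = 1) {
  if (T_total %% 2 != 0) stop("T_total must be even (equal halves)",
                              call. = FALSE)
  half <- T_total %/% 2
  covs <- list(block_correlation(6, list(1:3), r),
               block_correlation(6, list(4:6), r))
  labels1 <- rep(1:2, each = half)
  set.seed(as.integer(seed))
  series <- labels <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    Y <- rbind(rmvn0(half, covs[[1]]), rmvn0(half, covs[[2]]))
    series[[s]] <- Y
    labels[[s]] <- labels1
  }
  data <- roi_ts_set(series, tr_seconds)
  names(labels) <- names(data$subjects)
  list(data = data, labels = labels, state_covariances = covs)
}

#' Match decoded states to true labels
#'
#' Builds the overlap (confusion) matrix between decoded Viterbi states and
#' true simulation labels, assigns each true state a distinct decoded state
#' so as to maximize the total overlap (exact assignment by exhaustive
#' search when few states are decoded, greedy otherwise), and reports the
#' agreement: the fraction of time points whose decoded state maps onto the
#' true state.
#'
#' @param decoded list of `state_sequence` objects (or integer vectors).
#' @param truth list of integer vectors of true labels (same lengths).
#' @return list with `assignment` (named integer vector: decoded state for
#'   each true state), `agreement` (fraction in `[0, 1]`) and `overlap`
#'   (the full overlap matrix, decoded x true).
#' @export
match_state_labels <- function(decoded, truth) {
  dz <- unlist(lapply(decoded, path_of))
  tz <- unlist(lapply(truth, as.integer))
  if (length(dz) != length(tz)) {
    stop("decoded and true labels must cover the same time points",
         call. = FALSE)
  }
  Kd <- max(dz)
  Kt <- max(tz)
  O <- matrix(0, Kd, Kt)
  for (i in seq_along(dz)) O[dz[i], tz[i]] <- O[dz[i], tz[i]] + 1
  used <- which(rowSums(O) > 0)
  best <- NULL
  if (length(used) <= 8) {
    # Exact: try every injective map of true states into decoded states.
    cand <- if (length(used) >= Kt) utils::combn(used, Kt, simplify = FALSE)
            else list(used)
    for (set in cand) {
      perms <- permutations_of(set)
      for (p in perms) {
        p <- p[seq_len(min(length(p), Kt))]
        sc <- sum(O[cbind(p, seq_along(p))])
        if (is.null(best) || sc > best$score) {
          best <- list(score = sc, map = p)
        }
      }
    }
  } else {
    # Greedy fallback for many decoded states.
    map <- integer(Kt)
    Ow <- O
    for (rep_i in seq_len(Kt)) {
      idx <- which(Ow == max(Ow), arr.ind = TRUE)[1, ]
      map[idx[2]] <- idx[1]
      Ow[idx[1], ] <- -1
      Ow[, idx[2]] <- -1
    }
    best <- list(score = sum(O[cbind(map, seq_len(Kt))]), map = map)
  }
  assignment <- best$map
  names(assignment) <- paste0("true_", seq_along(assignment))
  list(assignment = assignment,
       agreement = best$score / length(tz),
       overlap = O)
}

# All permutations of a vector (small n only).
#' @noRd
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}
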