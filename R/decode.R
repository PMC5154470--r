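#' Viterbi decoding of the most probable state sequence
#'
#' Finds the maximum-probability state path for one subject under the
#' variational expected parameters (`exp(E[log pi])`, `exp(E[log A])` and
#' the expected emission log-densities), computed in log space. Ties are
#' broken toward the lower state index.
#'
#' @param post a fitted `vbhmm_posterior`.
#' @param series one subject's `T_s x M` matrix.
#' @param subject_id identifier stored with the result.
#' @return A `state_sequence`: list with `subject_id` and integer `path`
#'   (length `T_s`, values in `1..K`).
#' @export
viterbi <- function(post, series, subject_id = "subject") {
  ep <- expected_log_params(post)
  lrho <- ep$emission_loglik(as.matrix(series))
  Tn <- nrow(lrho); K <- ncol(lrho)
  delta <- ep$log_pi + lrho[1, ]
  back <- matrix(0L, Tn, K)
  if (Tn > 1) {
    for (t in 2:Tn) {
      # cand[k,j] = delta[j] + log A[j,k]; ties break to the lower index j.
      cand <- t(ep$log_A) + rep(delta, each = K)
      best_j <- max.col(pmax(cand, -.Machine$double.xmax),
                        ties.method = "first")
      back[t, ] <- best_j
      delta <- cand[cbind(seq_len(K), best_j)] + lrho[t, ]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1) {
    for (t in (Tn - 1):1) path[t] <- back[t + 1, path[t + 1]]
  }
  structure(list(subject_id = subject_id, path = path),
            class = "state_sequence")
}

#' Decode all subjects of a data set
#'
#' @param post a fitted `vbhmm_posterior`.
#' @param data a [roi_ts_set].
#' @return named list of `state_sequence` objects, one per subject.
#' @export
decode_states <- function(post, data) {
  stopifnot(inherits(data, "roi_ts_set"))
  out <- mapply(function(series, id) viterbi(post, series, id),
                data$subjects, names(data$subjects), SIMPLIFY = FALSE)
  out
}

#' @noRd
path_of <- function(x) if (inherits(x, "state_sequence")) x$path else as.integer(x)

#' State occupancy rates
#'
#' Percentage of time points assigned to each state by the Viterbi paths:
#' `100 * (number of time points in state k) / (total time points)`, pooled
#' over subjects at the group level. Percentages sum to exactly 100.
#'
#' @param paths list of `state_sequence` objects (or integer vectors).
#' @param K number of states.
#' @param by_subject if `TRUE`, return an `S x K` matrix of per-subject
#'   occupancies instead of the pooled group vector.
#' @return length-`K` percentage vector, or an `S x K` matrix.
#' @export
occupancy_rates <- function(paths, K, by_subject = FALSE) {
  if (inherits(paths, "state_sequence")) paths <- list(paths)
  if (length(paths) == 0) stop("`paths` must be non-empty", call. = FALSE)
  per <- t(vapply(paths, function(p) {
    z <- path_of(p)
    100 * tabulate(z, nbins = K) / length(z)
  }, numeric(K)))
  if (by_subject) return(per)
  counts <- Reduce(`+`, lapply(paths, function(p) tabulate(path_of(p), nbins = K)))
  total <- sum(vapply(paths, function(p) length(path_of(p)), integer(1)))
  100 * counts / total
}

# Run lengths of state k in an integer path.
#' @noRd
state_runs <- function(z, k) {
  r <- rle(z == k)
  r$lengths[r$values]
}

#' Mean state lifetimes
#'
#' The mean lifetime (dwell time) of a state is the average length of its
#' maximal contiguous runs, converted to seconds by the sampling interval.
#' Runs are pooled across subjects at the group level; runs truncated by the
#' start or end of a scan count as complete runs. States with no runs get a
#' lifetime of 0.
#'
#' @param paths list of `state_sequence` objects (or integer vectors).
#' @param K number of states.
#' @param tr_seconds sampling interval in seconds.
#' @param by_subject if `TRUE`, return an `S x K` matrix of per-subject mean
#'   lifetimes.
#' @return length-`K` vector of seconds, or an `S x K` matrix.
#' @export
mean_lifetimes <- function(paths, K, tr_seconds, by_subject = FALSE) {
  if (inherits(paths, "state_sequence")) paths <- list(paths)
  if (tr_seconds <= 0) stop("tr_seconds must be > 0", call. = FALSE)
  if (by_subject) {
    return(t(vapply(paths, function(p) {
      z <- path_of(p)
      vapply(seq_len(K), function(k) {
        runs <- state_runs(z, k)
        if (length(runs) == 0) 0 else mean(runs) * tr_seconds
      }, numeric(1))
    }, numeric(K))))
  }
  vapply(seq_len(K), function(k) {
    runs <- unlist(lapply(paths, function(p) state_runs(path_of(p), k)))
    if (length(runs) == 0) 0 else mean(runs) * tr_seconds
  }, numeric(1))
}

#' Subject-level state transition matrix from a Viterbi path
#'
#' Two estimators are provided. `mode = "mle"` (default) is the standard
#' frequentist estimator `C(i,j) / sum_j C(i,j)`, whose rows over visited
#' source states sum to 1. `mode = "as_printed"` follows the joint/marginal
#' construction `A(i,j) = p(i,j)/p(i)` with `p(i,j) = C(i,j)/(C(i) C(j))`
#' and `p(i) = C(i)/T`; note this form reduces to
#' `T * C(i,j) / (C(i)^2 C(j))` and its rows do not in general sum to 1 --
#' it is kept for fidelity with the originally described computation.
#' Unvisited source states yield all-zero rows.
#'
#' @param path a `state_sequence` or integer vector (length >= 2).
#' @param K number of states.
#' @param mode `"mle"` or `"as_printed"`.
#' @return `K x K` non-negative matrix.
#' @export
subject_transition_matrix <- function(path, K, mode = c("mle", "as_printed")) {
  mode <- match.arg(mode)
  z <- path_of(path)
  Tn <- length(z)
  if (Tn < 2) stop("path must have at least 2 time points", call. = FALSE)
  C2 <- matrix(0, K, K)
  for (t in 2:Tn) C2[z[t - 1], z[t]] <- C2[z[t - 1], z[t]] + 1
  C1 <- tabulate(z, nbins = K)
  A <- matrix(0, K, K)
  if (mode == "mle") {
    rs <- rowSums(C2)
    nz <- rs > 0
    A[nz, ] <- C2[nz, , drop = FALSE] / rs[nz]
  } else {
    for (i in seq_len(K)) for (j in seq_len(K)) {
      if (C1[i] > 0 && C1[j] > 0) {
        pij <- C2[i, j] / (C1[i] * C1[j])
        pi_ <- C1[i] / Tn
        A[i, j] <- pij / pi_
      }
    }
  }
  A
}

#' Summarize state dynamics across subjects
#'
#' Bundles the dynamics metrics derived from Viterbi paths: group and
#' per-subject occupancy rates, group and per-subject mean lifetimes, and
#' each subject's transition matrix. Group metrics pool counts/runs over
#' subjects; subject-level summaries report mean and SEM across subjects.
#'
#' @param paths list of `state_sequence` objects.
#' @param K number of states.
#' @param tr_seconds sampling interval in seconds.
#' @param transition_mode passed to [subject_transition_matrix()].
#' @return An object of class `vbhmm_dynamics` with elements
#'   `occupancy_pct`, `occupancy_by_subject`, `mean_lifetime_seconds`,
#'   `lifetime_by_subject`, `subject_transition` (list), `transition_mode`,
#'   `zero_states` (indices never visited) and `tr_seconds`.
#' @export
state_dynamics <- function(paths, K, tr_seconds,
                           transition_mode = c("mle", "as_printed")) {
  transition_mode <- match.arg(transition_mode)
  occ <- occupancy_rates(paths, K)
  structure(
    list(
      occupancy_pct = occ,
      occupancy_by_subject = occupancy_rates(paths, K, by_subject = TRUE),
      mean_lifetime_seconds = mean_lifetimes(paths, K, tr_seconds),
      lifetime_by_subject = mean_lifetimes(paths, K, tr_seconds,
                                           by_subject = TRUE),
      subject_transition = lapply(paths, subject_transition_matrix, K = K,
                                  mode = transition_mode),
      transition_mode = transition_mode,
      zero_states = which(occ == 0),
      tr_seconds = tr_seconds,
      K = K
    ),
    class = "vbhmm_dynamics"
  )
}

#' @export
print.vbhmm_dynamics <- function(x, ...) {
  nz <- which(x$occupancy_pct > 0)
  ord <- nz[order(x$occupancy_pct[nz], decreasing = TRUE)]
  cat("State dynamics over ", length(x$subject_transition), " subject(s): ",
      length(nz), " of ", x$K, " states visited (",
      length(x$zero_states), " pruned)\n", sep = "")
  df <- data.frame(state = ord,
                   occupancy_pct = round(x$occupancy_pct[ord], 2),
                   mean_lifetime_s = round(x$mean_lifetime_seconds[ord], 2))
  print(df, row.names = FALSE)
  invisible(x)
}
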