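#' Partial correlations from a covariance matrix
#'
#' Inverts the covariance to the precision matrix `P` and rescales it:
#' `pcorr(i,j) = -P(i,j) / sqrt(P(i,i) P(j,j))` off the diagonal, 1 on the
#' diagonal. Each entry is the correlation between two nodes conditioned on
#' all others.
#'
#' @param cov symmetric positive-definite `M x M` matrix.
#' @return `M x M` partial-correlation matrix (unit diagonal).
#' @export
partial_correlation <- function(cov) {
  cov <- as.matrix(cov)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    stop("covariance is not symmetric", call. = FALSE)
  }
  ev <- eigen(symmetrize(cov), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("covariance is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  P <- chol2inv(chol(symmetrize(cov)))
  d <- sqrt(diag(P))
  R <- -P / tcrossprod(d)
  diag(R) <- 1
  dimnames(R) <- dimnames(cov)
  symmetrize(R)
}

# Signed modularity matrix, "negative_asym" convention: the positive part
# is normalized by the total positive strength, the negative part by the
# total (positive + negative) strength, so negative weights carry less
# influence than positive ones.
#' @noRd
signed_modularity_matrix <- function(W, gamma = 1) {
  W <- symmetrize(as.matrix(W))
  diag(W) <- 0
  Wp <- pmax(W, 0)
  Wn <- -pmin(W, 0)
  sp <- sum(Wp)
  sn <- sum(Wn)
  B <- matrix(0, nrow(W), ncol(W))
  if (sp > 0) B <- B + (Wp - gamma * tcrossprod(rowSums(Wp)) / sp) / sp
  if (sn > 0) B <- B - (Wn - gamma * tcrossprod(rowSums(Wn)) / sn) / (sp + sn)
  symmetrize(B)
}

# One Louvain optimization of a generalized modularity matrix: local node
# moving in the given order, then aggregation, repeated until no gain.
#' @noRd
louvain_modmatrix <- function(B) {
  n <- nrow(B)
  labels <- seq_len(n)           # community of each original node
  Bc <- B                        # aggregated modularity matrix
  repeat {
    m <- nrow(Bc)
    comm <- seq_len(m)
    moved_any <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample.int(m)) {
        ci <- comm[i]
        # Strength of i toward each community (excluding i itself).
        s <- vapply(unique(comm), function(c) {
          sum(Bc[i, comm == c & seq_len(m) != i])
        }, numeric(1))
        names(s) <- unique(comm)
        gain <- s - s[as.character(ci)]
        best <- names(gain)[which.max(gain)]
        if (gain[best] > 1e-12 && best != as.character(ci)) {
          comm[i] <- as.integer(best)
          moved <- TRUE
          moved_any <- TRUE
        }
      }
      if (!moved) break
    }
    if (!moved_any) break
    # Aggregate communities into super-nodes.
    u <- unique(comm)
    map <- match(comm, u)
    Bnew <- matrix(0, length(u), length(u))
    for (a in seq_along(u)) for (b in seq_along(u)) {
      Bnew[a, b] <- sum(Bc[map == a, map == b, drop = FALSE])
    }
    labels <- map[labels]
    Bc <- Bnew
    if (nrow(Bc) == 1) break
  }
  labels
}

# Relabel a partition so labels appear as 1, 2, ... in node order.
#' @noRd
canonicalize_partition <- function(p) match(p, unique(p))

#' @noRd
partition_modularity <- function(B, p) {
  sum(B[outer(p, p, "==")])
}

#' Signed Louvain community detection
#'
#' Detects node communities in an unthresholded (partial-)correlation
#' matrix using a Louvain optimization of signed modularity in which
#' negative weights are treated asymmetrically: positive weights are
#' normalized by the total positive strength and negative weights by the
#' combined positive-plus-negative strength, so negative edges penalize
#' co-assignment more weakly than positive edges reward it. The diagonal is
#' zeroed before clustering (self-loops excluded). Because single-run
#' Louvain depends on the node visiting order, `n_runs` randomized restarts
#' are performed and the partition with maximal modularity is returned, with
#' labels canonicalized by first appearance.
#'
#' @param pcorr symmetric weight matrix (e.g. partial correlations).
#' @param seed integer seed for the restart stream.
#' @param n_runs number of randomized restarts (default 100).
#' @param gamma resolution parameter (default 1).
#' @return list with `partition` (integer labels, contiguous from 1) and
#'   `modularity` (the signed modularity of that partition).
#' @export
detect_communities <- function(pcorr, seed = 1, n_runs = 100, gamma = 1) {
  W <- as.matrix(pcorr)
  if (nrow(W) != ncol(W) || max(abs(W - t(W))) > 1e-8) {
    stop("`pcorr` must be a symmetric square matrix", call. = FALSE)
  }
  n <- nrow(W)
  B <- signed_modularity_matrix(W, gamma = gamma)
  if (all(B == 0)) {
    return(list(partition = seq_len(n), modularity = 0))
  }
  set.seed(as.integer(seed))
  best <- NULL
  diagQ <- sum(diag(B))  # constant under any partition; excluded from Q
  for (run in seq_len(n_runs)) {
    p <- louvain_modmatrix(B)
    q <- partition_modularity(B, p) - diagQ
    if (is.null(best) || q > best$q + 1e-12) best <- list(p = p, q = q)
  }
  list(partition = canonicalize_partition(best$p), modularity = best$q)
}

#' Do two partitions group the nodes identically?
#'
#' Label-permutation-invariant equality: `TRUE` iff the two labelings induce
#' the same equivalence relation on nodes.
#'
#' @param p1,p2 integer label vectors of equal length.
#' @return logical.
#' @export
partitions_equal <- function(p1, p2) {
  if (length(p1) != length(p2)) {
    stop("partitions must have equal length", call. = FALSE)
  }
  identical(canonicalize_partition(p1), canonicalize_partition(p2))
}

#' Per-state partial-correlation networks
#'
#' For every state with non-zero Viterbi occupancy, computes the
#' partial-correlation matrix from the state's expected covariance and its
#' signed-Louvain community partition. Zero-occupancy states are reported as
#' pruned and receive no network.
#'
#' @param post a fitted `vbhmm_posterior`.
#' @param paths list of `state_sequence` objects (for occupancy).
#' @param seed,n_runs,gamma passed to [detect_communities()].
#' @return list with `networks` (list of `state_network` objects: state_id,
#'   pcorr, partition, modularity, occupancy_pct) and `pruned` (indices of
#'   zero-occupancy states).
#' @export
state_networks <- function(post, paths, seed = 1, n_runs = 100, gamma = 1) {
  K <- post$K
  occ <- occupancy_rates(paths, K)
  active <- which(occ > 0)
  networks <- lapply(active, function(k) {
    pc <- partial_correlation(expected_covariance(post, k))
    cm <- detect_communities(pc, seed = seed, n_runs = n_runs, gamma = gamma)
    structure(list(state_id = k, pcorr = pc, partition = cm$partition,
                   modularity = cm$modularity, occupancy_pct = occ[k]),
              class = "state_network")
  })
  list(networks = networks, pruned = which(occ == 0))
}

#' Merge states sharing a community structure into dynamic functional
#' networks
#'
#' States whose partial-correlation networks induce the same node partition
#' are merged into one dynamic functional network (DFN); each subject's
#' Viterbi path is relabeled to DFN ids and all dynamics (occupancy, mean
#' lifetimes -- runs of sibling states fuse -- and transition matrices) are
#' recomputed on the merged paths. DFNs are ordered by descending group
#' occupancy. When `pool_mixed = TRUE`, every DFN at or below
#' `cutoff_pct` occupancy is pooled into a residual "mixed" DFN (listed
#' last, `is_mixed = TRUE`).
#'
#' @param networks list of `state_network` objects (from [state_networks()]).
#' @param paths list of `state_sequence` objects.
#' @param tr_seconds sampling interval in seconds.
#' @param cutoff_pct occupancy cutoff (percent) for pooling (default 15).
#' @param pool_mixed pool low-occupancy DFNs into a mixed DFN?
#' @param transition_mode passed to [subject_transition_matrix()].
#' @return list with `dfns` (list of `dfn` objects: dfn_id, member_states,
#'   partition, occupancy_pct, mean_lifetime_seconds, is_mixed), `paths`
#'   (merged `state_sequence` per subject), `dynamics` (a `vbhmm_dynamics`
#'   on the merged labels) and `transition` (group mean of subject
#'   transition matrices between DFNs).
#' @export
merge_states <- function(networks, paths, tr_seconds, cutoff_pct = 15,
                         pool_mixed = FALSE,
                         transition_mode = c("mle", "as_printed")) {
  transition_mode <- match.arg(transition_mode)
  if (length(networks) == 0) stop("no state networks supplied", call. = FALSE)
  state_ids <- vapply(networks, function(x) x$state_id, numeric(1))
  # Group states by partition equality.
  groups <- list()
  for (i in seq_along(networks)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (partitions_equal(networks[[groups[[g]][1]]]$partition,
                           networks[[i]]$partition)) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- i
  }
  occ_states <- vapply(networks, function(x) x$occupancy_pct, numeric(1))
  group_occ <- vapply(groups, function(g) sum(occ_states[g]), numeric(1))
  groups <- groups[order(group_occ, decreasing = TRUE)]
  group_occ <- sort(group_occ, decreasing = TRUE)
  if (pool_mixed && any(group_occ <= cutoff_pct) &&
      sum(group_occ <= cutoff_pct) > 1) {
    low <- which(group_occ <= cutoff_pct)
    pooled <- unlist(groups[low])
    groups <- c(groups[-low], list(pooled))
  }
  n_dfn <- length(groups)
  mixed_flag <- rep(FALSE, n_dfn)
  if (pool_mixed && exists("pooled", inherits = FALSE)) {
    mixed_flag[n_dfn] <- TRUE
  }
  # Map each original state to its DFN id (unmerged states keep NA -> they
  # have zero occupancy and never occur in paths).
  K_old <- max(unlist(lapply(paths, path_of)))
  state_to_dfn <- rep(NA_integer_, max(K_old, max(state_ids)))
  for (d in seq_len(n_dfn)) {
    for (i in groups[[d]]) state_to_dfn[state_ids[i]] <- d
  }
  merged_paths <- lapply(paths, function(p) {
    z <- path_of(p)
    newz <- state_to_dfn[z]
    if (any(is.na(newz))) {
      stop("a decoded state has no network; pass networks covering all ",
           "states with non-zero occupancy", call. = FALSE)
    }
    structure(list(subject_id = if (inherits(p, "state_sequence"))
      p$subject_id else "subject", path = as.integer(newz)),
      class = "state_sequence")
  })
  dyn <- state_dynamics(merged_paths, K = n_dfn, tr_seconds = tr_seconds,
                        transition_mode = transition_mode)
  trans_group <- Reduce(`+`, dyn$subject_transition) /
    length(dyn$subject_transition)
  dfns <- lapply(seq_len(n_dfn), function(d) {
    members <- state_ids[groups[[d]]]
    structure(list(
      dfn_id = d,
      member_states = members,
      partition = networks[[groups[[d]][1]]]$partition,
      occupancy_pct = dyn$occupancy_pct[d],
      mean_lifetime_seconds = dyn$mean_lifetime_seconds[d],
      is_mixed = mixed_flag[d]
    ), class = "dfn")
  })
  list(dfns = dfns, paths = merged_paths, dynamics = dyn,
       transition = trans_group)
}

#' Within- vs cross-network link strength
#'
#' Splits the unordered node pairs of a (partial-)correlation matrix by a
#' node-to-static-network label map and averages the link weights within
#' each type: within-network links connect nodes with equal labels,
#' cross-network links connect nodes with different labels.
#'
#' @param pcorr symmetric matrix.
#' @param node_networks character vector of static-network labels, one per
#'   node (order matching the matrix), or a named vector matching the
#'   matrix's dimnames.
#' @return list with `within_mean` and `cross_mean`; a type with no links is
#'   `NA` with a warning.
#' @export
classify_links <- function(pcorr, node_networks) {
  W <- as.matrix(pcorr)
  n <- nrow(W)
  if (!is.null(names(node_networks)) && !is.null(rownames(W))) {
    if (!all(rownames(W) %in% names(node_networks))) {
      stop("node map does not cover all nodes: missing ",
           paste(setdiff(rownames(W), names(node_networks)), collapse = ", "),
           call. = FALSE)
    }
    node_networks <- node_networks[rownames(W)]
  }
  if (length(node_networks) != n) {
    stop("need one network label per node", call. = FALSE)
  }
  ut <- upper.tri(W)
  same <- outer(node_networks, node_networks, "==")
  within <- W[ut & same]
  cross <- W[ut & !same]
  within_mean <- if (length(within)) mean(within) else NA_real_
  cross_mean <- if (length(cross)) mean(cross) else NA_real_
  if (is.na(within_mean)) warning("no within-network links", call. = FALSE)
  if (is.na(cross_mean)) warning("no cross-network links", call. = FALSE)
  list(within_mean = within_mean, cross_mean = cross_mean)
}
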