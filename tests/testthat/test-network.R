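test_that("partial correlations: independence, bivariate closed form, chain", {
  expect_equal(partial_correlation(diag(c(2, 3, 4))), diag(3))

  # Bivariate: pcorr(1,2) equals the plain correlation r for any |r| < 1.
  for (r in c(-0.9, -0.3, 0, 0.42, 0.8)) {
    C <- matrix(c(1, r, r, 1), 2, 2)
    expect_equal(partial_correlation(C)[1, 2], r, tolerance = 1e-12)
  }

  # 3-node chain: build the covariance from a known precision matrix; the
  # partial correlations must recover the scaled negated precision pattern.
  P <- matrix(c(1, -0.5, 0, -0.5, 1, -0.5, 0, -0.5, 1), 3, 3)
  C <- solve(P)
  pc <- partial_correlation(C)
  expect_equal(pc[1, 2], 0.5, tolerance = 1e-8)
  expect_equal(pc[2, 3], 0.5, tolerance = 1e-8)
  expect_equal(pc[1, 3], 0, tolerance = 1e-8)
  expect_equal(diag(pc), rep(1, 3))

  expect_error(partial_correlation(matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("partial correlation round-trips a random precision matrix", {
  set.seed(50)
  for (i in 1:5) {
    M <- sample(3:6, 1)
    A <- matrix(rnorm(M * M), M, M)
    P <- crossprod(A) + M * diag(M)
    pc <- partial_correlation(solve(P))
    d <- sqrt(diag(P))
    want <- -P / tcrossprod(d)
    diag(want) <- 1
    expect_equal(pc, want, tolerance = 1e-8)
  }
})

test_that("signed Louvain finds the exhaustive-search optimum on planted blocks", {
  W <- planted_signed_blocks(6, within = 0.8, between = -0.2)
  oracle <- best_partition_oracle(W)
  got <- detect_communities(W, seed = 1, n_runs = 20)
  expect_partitions_equal(got$partition, oracle$partition)
  expect_partitions_equal(got$partition, rep(1:2, each = 3))
  expect_equal(got$modularity, oracle$modularity, tolerance = 1e-12)
})

test_that("signed Louvain recovers planted blocks on every seed", {
  W <- planted_signed_blocks(6, within = 0.6, between = -0.1)
  for (s in 1:20) {
    got <- detect_communities(W, seed = s, n_runs = 10)
    expect_partitions_equal(got$partition, rep(1:2, each = 3))
  }
})

test_that("community detection edge cases and equivariance", {
  # No off-diagonal weights: every node is its own community.
  got <- detect_communities(diag(4) * 0, seed = 1, n_runs = 5)
  expect_equal(got$partition, 1:4)
  expect_equal(got$modularity, 0)

  pc <- diag(5)
  got2 <- detect_communities(pc, seed = 1, n_runs = 5)
  expect_equal(got2$partition, 1:5)

  # Permuting nodes permutes the partition identically.
  set.seed(51)
  W <- planted_signed_blocks(6, 0.7, -0.15)
  perm <- sample(6)
  p1 <- detect_communities(W, seed = 3, n_runs = 10)$partition
  p2 <- detect_communities(W[perm, perm], seed = 3, n_runs = 10)$partition
  expect_partitions_equal(p1[perm], p2)
})

test_that("partition equality is label-permutation invariant", {
  expect_true(partitions_equal(c(1, 1, 2), c(2, 2, 1)))
  expect_false(partitions_equal(c(1, 1, 2), c(1, 2, 2)))
  expect_true(partitions_equal(c(1, 2, 3), c(3, 1, 2)))
  expect_error(partitions_equal(c(1, 2), c(1, 2, 3)), "equal length")
})

fake_network <- function(id, partition, occ) {
  M <- length(partition)
  structure(list(state_id = id, pcorr = diag(M), partition = partition,
                 modularity = 0.1, occupancy_pct = occ),
            class = "state_network")
}

test_that("states with equal partitions merge and conserve occupancy", {
  # States 1 and 2 share a partition; state 3 differs.
  paths <- list(structure(list(subject_id = "a",
                               path = rep(c(1L, 2L, 3L, 2L), 5)),
                          class = "state_sequence"))
  occ <- occupancy_rates(paths, 3)
  nets <- list(fake_network(1, c(1, 1, 2), occ[1]),
               fake_network(2, c(2, 2, 1), occ[2]),
               fake_network(3, c(1, 2, 3), occ[3]))
  merged <- merge_states(nets, paths, tr_seconds = 1)
  occ_dfn <- vapply(merged$dfns, function(d) d$occupancy_pct, numeric(1))
  expect_equal(sum(occ_dfn), 100)
  expect_equal(length(merged$dfns), 2)
  expect_equal(sort(merged$dfns[[1]]$member_states), c(1, 2))
  expect_equal(occ_dfn[1], occ[1] + occ[2])
})

test_that("merging fuses runs: lifetimes recomputed on merged labels", {
  paths <- list(structure(list(subject_id = "a", path = rep(c(1L, 2L), 10)),
                          class = "state_sequence"))
  nets <- list(fake_network(1, c(1, 1, 2), 50),
               fake_network(2, c(2, 2, 1), 50))
  merged <- merge_states(nets, paths, tr_seconds = 0.5)
  expect_equal(length(merged$dfns), 1)
  # The alternating 1,2,1,2,... path becomes one run of length 20.
  expect_equal(merged$dfns[[1]]$mean_lifetime_seconds, 20 * 0.5)
  expect_equal(merged$paths[[1]]$path, rep(1L, 20))
})

test_that("distinct partitions leave states unmerged, metrics unchanged", {
  paths <- list(structure(list(subject_id = "a",
                               path = c(rep(1L, 6), rep(2L, 4))),
                          class = "state_sequence"))
  nets <- list(fake_network(1, c(1, 1, 2), 60), fake_network(2, c(1, 2, 2), 40))
  merged <- merge_states(nets, paths, tr_seconds = 1)
  expect_equal(length(merged$dfns), 2)
  expect_equal(vapply(merged$dfns, function(d) d$occupancy_pct, numeric(1)),
               c(60, 40))
  expect_equal(merged$paths[[1]]$path, paths[[1]]$path)
})

test_that("low-occupancy DFNs pool into a mixed DFN when requested", {
  paths <- list(structure(list(
    subject_id = "a",
    path = c(rep(1L, 60), rep(2L, 26), rep(3L, 8), rep(4L, 6))),
    class = "state_sequence"))
  occ <- occupancy_rates(paths, 4)
  nets <- lapply(1:4, function(k) {
    parts <- list(c(1, 1, 2), c(1, 2, 2), c(1, 2, 1), c(1, 1, 1))
    fake_network(k, parts[[k]], occ[k])
  })
  merged <- merge_states(nets, paths, tr_seconds = 1, cutoff_pct = 15,
                         pool_mixed = TRUE)
  expect_equal(length(merged$dfns), 3)
  expect_true(merged$dfns[[3]]$is_mixed)
  expect_equal(sort(merged$dfns[[3]]$member_states), c(3, 4))
  expect_equal(merged$dfns[[3]]$occupancy_pct, occ[3] + occ[4])
  expect_equal(sum(vapply(merged$dfns, function(d) d$occupancy_pct,
                          numeric(1))), 100)
})

test_that("link classification splits within- and cross-network pairs", {
  # 4 nodes, labels (A,A,B,B), upper triangle filled row-wise.
  W <- diag(4)
  W[1, 2] <- 0.6; W[1, 3] <- 0.1; W[1, 4] <- 0.2
  W[2, 3] <- 0.3; W[2, 4] <- 0.4; W[3, 4] <- 0.7
  W <- W + t(W) - diag(4)
  got <- classify_links(W, c("A", "A", "B", "B"))
  expect_equal(got$within_mean, (0.6 + 0.7) / 2)
  expect_equal(got$cross_mean, (0.1 + 0.2 + 0.3 + 0.4) / 4)

  # Three pairs with 0.5 inside each pair, 0 elsewhere.
  W2 <- diag(6)
  for (i in c(1, 3, 5)) W2[i, i + 1] <- W2[i + 1, i] <- 0.5
  got2 <- classify_links(W2, rep(c("SN", "CEN", "DMN"), each = 2))
  expect_equal(got2$within_mean, 0.5)
  expect_equal(got2$cross_mean, 0)

  # All nodes in one network: no cross links, flagged as NA.
  expect_warning(got3 <- classify_links(W2, rep("SN", 6)), "cross")
  expect_true(is.na(got3$cross_mean))
  expect_error(classify_links(W2, c("A", "B")), "label per node")
})
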