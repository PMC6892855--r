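# Modularity, the two community-detection algorithms, and partition
# comparison.

test_that("modularity matches closed forms", {
  # trivial one-community partition: Q = 0 on arbitrary graphs
  set.seed(2)
  for (r in 1:5) {
    W <- matrix(0, 7, 7)
    W[upper.tri(W)] <- stats::runif(21) * (stats::runif(21) < 0.5)
    W <- W + t(W)
    expect_equal(modularity_q(W, rep(1, 7)), 0, tolerance = 1e-14)
  }
  # two disconnected unit triangles
  W <- two_triangles()
  expect_equal(modularity_q(W, c(1, 1, 1, 2, 2, 2)), 0.5, tolerance = 1e-14)
  expect_equal(modularity_q(W, 1:6), -1 / 6, tolerance = 1e-14)
  # all-zero network: Q defined as 0 with a warning
  expect_warning(q0 <- modularity_q(matrix(0, 4, 4), c(1, 1, 2, 2)),
                 "no division")
  expect_equal(q0, 0)
})

test_that("modularity agrees with igraph on weighted graphs", {
  set.seed(8)
  W <- matrix(0, 8, 8)
  W[upper.tri(W)] <- stats::runif(28) * (stats::runif(28) < 0.4)
  W <- W + t(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  mem <- sample(1:3, 8, replace = TRUE)
  expect_equal(modularity_q(W, mem),
               igraph::modularity(g, mem, weights = igraph::E(g)$weight),
               tolerance = 1e-12)
})

test_that("both algorithms split two cliques at the bridge", {
  # two 4-cliques joined by one weak bridge
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  W[4, 5] <- W[5, 4] <- 0.1
  planted <- rep(1:2, each = 4)
  for (part in list(walktrap_communities(W),
                    edge_betweenness_communities(W))) {
    expect_equal(part$n_communities, 2)
    expect_equal(adjusted_rand_index(part$membership, planted), 1)
    # matches the exhaustive-search maximum
    exh <- exhaustive_modularity(W)
    expect_equal(part$modularity_Q, exh$q, tolerance = 1e-12)
  }
})

test_that("uniform complete and star graphs yield the trivial partition", {
  K <- matrix(1, 6, 6); diag(K) <- 0
  exh <- exhaustive_modularity(K)
  expect_lte(exh$q, 0 + 1e-12)   # no cut beats the trivial partition
  for (part in list(walktrap_communities(K),
                    edge_betweenness_communities(K))) {
    expect_equal(part$n_communities, 1)
    expect_equal(part$modularity_Q, 0)
  }
  S <- matrix(0, 6, 6); S[1, 2:6] <- 1; S <- S + t(S)
  expect_lte(exhaustive_modularity(S)$q, 1e-12)
  expect_equal(walktrap_communities(S)$n_communities, 1)
  expect_equal(edge_betweenness_communities(S)$n_communities, 1)
})

test_that("returned Q attains the exhaustive maximum on random sparse fixtures", {
  set.seed(14)
  for (r in 1:5) {
    W <- matrix(0, 7, 7)
    W[upper.tri(W)] <- round(stats::runif(21), 2) * (stats::runif(21) < 0.35)
    W <- W + t(W)
    if (sum(W) == 0) next
    exh <- exhaustive_modularity(W)
    wt <- walktrap_communities(W)
    eb <- edge_betweenness_communities(W)
    # the agglomerative/divisive cuts cannot beat the global optimum, and on
    # these small fixtures they are expected to attain it
    expect_lte(wt$modularity_Q, exh$q + 1e-12)
    expect_lte(eb$modularity_Q, exh$q + 1e-12)
    expect_equal(max(wt$modularity_Q, eb$modularity_Q), exh$q,
                 tolerance = 1e-9)
  }
})

test_that("negative weights are analysed through their absolute values", {
  W <- two_triangles()
  Wn <- W
  Wn[1, 2] <- Wn[2, 1] <- -1   # sign flip must not change the partition
  p1 <- walktrap_communities(W)
  p2 <- walktrap_communities(Wn)
  expect_equal(p1$membership, p2$membership)
  expect_equal(p1$modularity_Q, p2$modularity_Q)
})

test_that("partitions are invariant under node relabeling", {
  W <- two_triangles(bridge = 0.1)
  perm <- c(4, 1, 6, 2, 5, 3)
  Wp <- W[perm, perm]
  p0 <- walktrap_communities(W)
  pp <- walktrap_communities(Wp)
  expect_equal(adjusted_rand_index(p0$membership[rownames(Wp)],
                                   pp$membership), 1)
  expect_equal(p0$modularity_Q, pp$modularity_Q, tolerance = 1e-12)
})

test_that("empty networks return the single trivial partition", {
  for (f in list(walktrap_communities, edge_betweenness_communities)) {
    part <- f(matrix(0, 5, 5))
    expect_equal(part$n_communities, 1)
    expect_equal(part$modularity_Q, 0)
  }
})

test_that("both algorithms recover the planted communities of the default truth", {
  gt <- default_ground_truth()
  planted <- stats::setNames(rep(3, 11), gt$nodes)
  planted[c("DEP", "NCOG", "WOR", "FEAR")] <- 1
  planted[c("ATT", "HYP", "IMP")] <- 2
  for (part in list(walktrap_communities(gt$couplings),
                    edge_betweenness_communities(gt$couplings))) {
    expect_gt(part$modularity_Q, 0.30)
    mem <- part$membership
    expect_length(unique(mem[c("DEP", "NCOG", "WOR", "FEAR")]), 1)
    expect_length(unique(mem[c("ATT", "HYP", "IMP")]), 1)
    expect_false(mem[["DEP"]] == mem[["ATT"]])
    # unconnected domains sit outside both planted communities
    expect_false(any(mem[c("FAT", "SUB", "PAIN", "EDYS")] %in%
                       mem[c("DEP", "ATT")]))
  }
})

test_that("adjusted Rand index matches the contingency-table formula and mclust", {
  a <- c(1, 1, 2, 2, 3, 3, 3)
  b <- c(2, 2, 2, 1, 1, 3, 3)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2)); ni <- sum(choose(rowSums(tab), 2))
  nj <- sum(choose(colSums(tab), 2)); nn <- choose(7, 2)
  oracle <- (nij - ni * nj / nn) / ((ni + nj) / 2 - ni * nj / nn)
  expect_equal(adjusted_rand_index(a, b), oracle, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
  expect_equal(adjusted_rand_index(a, a), 1)
  # relabeling invariance
  expect_equal(adjusted_rand_index(a, c(2, 2, 1, 1, 9, 9, 9)), 1)
})

test_that("community_report summarises groups and flags clear structure", {
  W <- two_triangles()
  p1 <- walktrap_communities(W)              # Q = 0.5
  p2 <- walktrap_communities(matrix(0, 6, 6))  # trivial, Q = 0
  p2$modularity_Q <- 0.29                     # borderline handling
  p3 <- p1; p3$modularity_Q <- 0.34
  rep_ <- community_report(list(g1 = p1, g2 = p2, g3 = p3))
  expect_equal(rep_$summary$clear_structure, c(TRUE, FALSE, TRUE))
  expect_equal(rep_$ari["g1", "g3"], 1)
  expect_equal(dim(rep_$membership), c(6L, 3L))
  same <- community_report(list(a = p1, b = p1, c = p1))
  expect_true(all(same$ari == 1))
})
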