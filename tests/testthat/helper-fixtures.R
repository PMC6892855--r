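# Shared fixtures, all built in code.

# p-node chain with constant couplings: 1-2-3-...-p
chain_network <- function(p = 6, coupling = 1.5, threshold = -0.75) {
  B <- matrix(0, p, p)
  for (i in seq_len(p - 1)) B[i, i + 1] <- B[i + 1, i] <- coupling
  ground_truth_network(B, rep(threshold, p))
}

# two unit-weight triangles, optionally joined by a weak bridge (3-4)
two_triangles <- function(bridge = 0) {
  W <- matrix(0, 6, 6)
  cl <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  for (k in seq_len(nrow(cl))) W[cl[k, 1], cl[k, 2]] <- W[cl[k, 2], cl[k, 1]] <- 1
  if (bridge > 0) W[3, 4] <- W[4, 3] <- bridge
  dimnames(W) <- list(paste0("n", 1:6), paste0("n", 1:6))
  W
}

# wrap a weight matrix as an ising_network for the comparison operations
as_ising_net <- function(W, rule = "AND") {
  W <- as.matrix(W)
  nodes <- rownames(W)
  if (is.null(nodes)) {
    nodes <- paste0("V", seq_len(nrow(W)))
    dimnames(W) <- list(nodes, nodes)
  }
  structure(list(weights = W, intercepts = stats::setNames(rep(0, nrow(W)), nodes),
                 nodes = nodes, dropped = character(), n_fit = NA_integer_,
                 gamma = 0.25, rule = rule, weighted = TRUE),
            class = "ising_network")
}

# strongly coupled two-community network (triangle + triangle) used as the
# "planted strength difference" alternative in comparison-test checks
strong_two_community_net <- function(coupling = 1.0, threshold = -1.5) {
  B <- two_triangles() * coupling
  dimnames(B) <- NULL
  ground_truth_network(B, rep(threshold, 6))
}
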