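# Modularity-based community detection on estimated symptom networks.
# Edge weights are consumed as absolute values: modularity is undefined for
# negative weights, and estimated symptom-domain networks here are
# overwhelmingly positive.

as_weight_matrix <- function(net) {
  W <- if (inherits(net, "ising_network")) net$weights else as.matrix(net)
  if (is.null(rownames(W)))
    dimnames(W) <- list(paste0("V", seq_len(nrow(W))),
                        paste0("V", seq_len(nrow(W))))
  abs(W)
}

#' Newman weighted modularity of a partition
#'
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left(A_{ij} - \frac{k_i k_j}{2m}\right)
#'   \delta(c_i, c_j)}
#' the difference between the within-community edge weight of the network
#' and its expectation under a degree-preserving random graph. Q = 0 for the
#' trivial all-in-one partition on any input; values above about 0.30 are
#' conventionally read as clear community structure.
#'
#' @param net An `ising_network` or symmetric weight matrix (absolute values
#'   are used).
#' @param membership Integer (or factor) community assignment covering all
#'   nodes.
#' @return Q in [-1, 1]; 0 (with a warning) for an all-zero network, which
#'   admits no division into subnetworks.
#' @export
modularity_q <- function(net, membership) {
  A <- as_weight_matrix(net)
  p <- nrow(A)
  if (length(membership) != p)
    stop("membership must cover all ", p, " nodes")
  m2 <- sum(A)  # 2m: each undirected edge counted twice
  if (m2 == 0) {
    warning("all-zero network: no division into subnetworks exists; Q = 0")
    return(0)
  }
  k <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

make_partition <- function(net, membership, algorithm, parameters = list(),
                           q = NULL) {
  A <- as_weight_matrix(net)
  membership <- as.integer(factor(membership, levels = unique(membership)))
  names(membership) <- rownames(A)
  structure(list(membership = membership,
                 n_communities = length(unique(membership)),
                 modularity_Q = if (is.null(q))
                   suppressWarnings(modularity_q(net, membership)) else q,
                 algorithm = algorithm, parameters = parameters),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("Partition (", x$algorithm, "): ", x$n_communities,
      " communities, Q = ", format(round(x$modularity_Q, 4)), "\n", sep = "")
  print(split(names(x$membership), x$membership))
  invisible(x)
}

# Evaluate every cut of a hierarchical igraph communities object with the
# package's own weighted Q and return the best; ties go to fewer communities.
best_cut <- function(comm, g, A) {
  p <- nrow(A)
  ks <- seq.int(length(unique(igraph::components(g)$membership)), p)
  best_q <- -Inf
  best_mem <- rep(1L, p)
  for (k in rev(ks)) {  # descending k so ties resolve to the smallest k
    mem <- suppressWarnings(igraph::cut_at(comm, no = k))
    q <- suppressWarnings(modularity_q(A, mem))
    if (q >= best_q - 1e-12) { best_q <- max(q, best_q); best_mem <- mem }
  }
  # the trivial partition always scores 0; never return a negative-Q cut
  if (best_q < 0) { best_mem <- rep(1L, p); best_q <- 0 }
  list(membership = best_mem, q = best_q)
}

#' Walktrap community detection
#'
#' Agglomerative merging driven by short random-walk distances; the returned
#' partition is the cut of the merge tree that maximises the package's
#' weighted modularity (ties broken toward fewer communities). Deterministic
#' for a fixed input. An empty network returns the single trivial partition
#' with Q = 0.
#'
#' @param net An `ising_network` or symmetric weight matrix; absolute
#'   weights are used as random-walk affinities.
#' @param walk_length Random-walk length (default 4).
#' @return A `partition`.
#' @export
walktrap_communities <- function(net, walk_length = 4L) {
  A <- as_weight_matrix(net)
  if (sum(A) == 0)
    return(make_partition(net, rep(1L, nrow(A)), "walktrap",
                          list(walk_length = walk_length), q = 0))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  comm <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                   steps = walk_length)
  cut <- best_cut(comm, g, A)
  make_partition(net, cut$membership, "walktrap",
                 list(walk_length = walk_length), q = cut$q)
}

#' Girvan-Newman (edge betweenness) community detection
#'
#' Divisive removal of the edge with the highest shortest-path betweenness;
#' edge weights are transformed to distances as 1/weight, so strong edges
#' are short. The returned partition is the stage of the removal sequence
#' maximising the package's weighted modularity.
#'
#' @inheritParams walktrap_communities
#' @return A `partition`.
#' @export
edge_betweenness_communities <- function(net) {
  A <- as_weight_matrix(net)
  if (sum(A) == 0)
    return(make_partition(net, rep(1L, nrow(A)), "edge_betweenness",
                          list(distance = "1/weight"), q = 0))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  comm <- suppressWarnings(
    igraph::cluster_edge_betweenness(g, weights = 1 / igraph::E(g)$weight,
                                     modularity = FALSE))
  cut <- best_cut(comm, g, A)
  make_partition(net, cut$membership, "edge_betweenness",
                 list(distance = "1/weight"), q = cut$q)
}

#' Exhaustive modularity maximisation (validation oracle)
#'
#' Enumerates every set partition of the nodes (feasible for p <= 10) and
#' returns the global maximum of the weighted modularity. Used to verify
#' that the polynomial-time algorithms attain the optimum on small fixtures.
#'
#' @param net An `ising_network` or symmetric weight matrix.
#' @return List with `membership`, `q`.
#' @export
exhaustive_modularity <- function(net) {
  A <- as_weight_matrix(net)
  p <- nrow(A)
  if (p > 10) stop("exhaustive search is limited to p <= 10 nodes")
  best_q <- -Inf
  best <- rep(1L, p)
  # enumerate set partitions as restricted growth strings
  rgs <- rep(1L, p)
  repeat {
    q <- suppressWarnings(modularity_q(A, rgs))
    if (q > best_q) { best_q <- q; best <- rgs }
    # next restricted growth string
    i <- p
    while (i > 1 && rgs[i] > max(rgs[1:(i - 1)])) i <- i - 1
    if (i == 1) break
    rgs[i] <- rgs[i] + 1L
    if (i < p) rgs[(i + 1):p] <- 1L
  }
  list(membership = stats::setNames(best, rownames(A)), q = best_q)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two community assignments over the same
#' node set, computed from the contingency table of co-memberships; 1 for
#' identical partitions, about 0 for independent ones.
#'
#' @param a,b Two membership vectors of equal length.
#' @return The ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must cover the same nodes")
  tab <- table(a, b)
  n <- length(a)
  s <- function(x) sum(choose(x, 2))
  sij <- s(tab); si <- s(rowSums(tab)); sj <- s(colSums(tab))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)  # both partitions trivial in the same way
  (sij - expected) / (mx - expected)
}

#' Cross-group community summary
#'
#' Per group: number of communities, modularity Q, and a clear-structure
#' flag (Q above the conventional 0.30 threshold). Across groups: pairwise
#' adjusted Rand indices and the per-node community-membership trajectory.
#'
#' @param partitions Named list of `partition` objects (one per group) over
#'   the same node set.
#' @param threshold Clear-structure modularity threshold (default 0.30).
#' @return A `community_report`: `summary` data frame, `ari` matrix,
#'   `membership` node x group table.
#' @export
community_report <- function(partitions, threshold = 0.30) {
  stopifnot(length(partitions) >= 1)
  if (is.null(names(partitions)))
    names(partitions) <- paste0("group", seq_along(partitions))
  summ <- data.frame(
    group = names(partitions),
    n_communities = vapply(partitions, function(p) p$n_communities, 0L),
    modularity_Q = vapply(partitions, function(p) p$modularity_Q, 0),
    algorithm = vapply(partitions, function(p) p$algorithm, ""),
    row.names = NULL)
  summ$clear_structure <- summ$modularity_Q > threshold
  K <- length(partitions)
  ari <- matrix(NA_real_, K, K,
                dimnames = list(names(partitions), names(partitions)))
  for (i in seq_len(K)) for (j in seq_len(K))
    ari[i, j] <- adjusted_rand_index(partitions[[i]]$membership,
                                     partitions[[j]]$membership)
  membership <- vapply(partitions, function(p) p$membership,
                       integer(length(partitions[[1]]$membership)))
  structure(list(summary = summ, ari = ari, membership = membership,
                 threshold = threshold),
            class = "community_report")
}

#' @export
print.community_report <- function(x, ...) {
  cat("Community report (clear structure: Q > ", x$threshold, ")\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}
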