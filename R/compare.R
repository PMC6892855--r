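# Pairwise comparison of group networks: permutation test of the global
# strength difference, edge-weight rank correlation, and Jaccard overlap
# of edge sets.

# Fast internal refit used inside permutation/bootstrap loops: skips input
# validation, drops constant nodes silently, returns the symmetric weight
# matrix and whether any node was dropped.
fit_weights_fast <- function(X, gamma, rule, n_lambda, lambda_ratio,
                             tol = 1e-7, max_iter = 200L) {
  p <- ncol(X)
  if (!is.double(X)) storage.mode(X) <- "double"
  cm <- .colMeans(X, nrow(X), p)
  keep <- which(cm > 0 & cm < 1)
  W <- matrix(0, p, p)
  if (length(keep) >= 2) {
    Xk <- if (length(keep) == p) X else X[, keep, drop = FALSE]
    fit <- elasso_nodewise_cpp(Xk, gamma, as.integer(n_lambda), lambda_ratio,
                               tol, as.integer(max_iter))
    B <- fit$directed
    tB <- t(B)
    present <- if (rule == "AND") (B != 0) & (tB != 0)
               else (B != 0) | (tB != 0)
    Wk <- (B + tB) * 0.5 * present
    diag(Wk) <- 0
    W[keep, keep] <- Wk
  }
  list(weights = W, n_dropped = p - length(keep))
}

#' Permutation test of the global-strength difference between two groups
#'
#' Pools the individuals of both groups and, for each permutation, randomly
#' regroups them into two groups of the original sizes, refits both networks
#' with identical estimator settings, and records the absolute difference in
#' global strength. The p-value uses the permutation-inclusive add-one
#' estimator `p = (1 + #[perm >= obs]) / (1 + n_permutations)`, whose
#' smallest attainable value is `1 / (n_permutations + 1)`.
#'
#' Permutations that leave a node constant in one regrouped sample drop that
#' node for that refit only; the number of such events is reported rather
#' than resampled away (resampling would bias the null distribution).
#'
#' @param binary_a,binary_b `binary_matrix` objects (or 0/1 matrices) with
#'   the same node set.
#' @param n_permutations Number of regroupings (default 10000).
#' @param seed Optional seed for the permutation stream.
#' @param gamma,rule,n_lambda,lambda_ratio Estimator settings applied
#'   identically to every fit.
#' @param weighted If FALSE, the statistic is the unweighted global strength
#'   (edge count) of the fitted networks.
#' @return An `nct_result`: observed strengths and difference, permutation
#'   differences, `p_value`, `n_constant_events`.
#' @export
nct_global_strength <- function(binary_a, binary_b, n_permutations = 10000L,
                                seed = NULL, gamma = 0.25,
                                rule = c("AND", "OR"), n_lambda = 100L,
                                lambda_ratio = 0.01, weighted = TRUE) {
  rule <- match.arg(rule)
  A <- if (inherits(binary_a, "binary_matrix")) binary_a$values else as.matrix(binary_a)
  B <- if (inherits(binary_b, "binary_matrix")) binary_b$values else as.matrix(binary_b)
  if (ncol(A) != ncol(B) ||
      (!is.null(colnames(A)) && !is.null(colnames(B)) &&
       !identical(colnames(A), colnames(B))))
    stop("the two groups must share the same node set")
  stat <- function(W) if (weighted) sum(abs(W[upper.tri(W)]))
                      else sum(W[upper.tri(W)] != 0)
  n_a <- nrow(A); n_b <- nrow(B)
  pool <- rbind(A, B)
  storage.mode(pool) <- "double"  # avoid per-permutation conversions
  fa <- fit_weights_fast(A, gamma, rule, n_lambda, lambda_ratio)
  fb <- fit_weights_fast(B, gamma, rule, n_lambda, lambda_ratio)
  s_obs <- c(stat(fa$weights), stat(fb$weights))
  obs <- abs(s_obs[1] - s_obs[2])
  if (!is.null(seed)) set.seed(seed)
  perm <- numeric(n_permutations)
  n_const <- 0L
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(n_a + n_b, n_a)
    pa <- fit_weights_fast(pool[idx, , drop = FALSE], gamma, rule,
                           n_lambda, lambda_ratio)
    pb <- fit_weights_fast(pool[-idx, , drop = FALSE], gamma, rule,
                           n_lambda, lambda_ratio)
    n_const <- n_const + (pa$n_dropped > 0L) + (pb$n_dropped > 0L)
    perm[b] <- abs(stat(pa$weights) - stat(pb$weights))
  }
  structure(list(observed_strengths = s_obs, observed_difference = obs,
                 n_permutations = n_permutations,
                 permutation_differences = perm,
                 p_value = (1 + sum(perm >= obs)) / (1 + n_permutations),
                 n_constant_events = n_const, seed = seed,
                 weighted = weighted),
            class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat("Global strength permutation test (", x$n_permutations,
      " permutations", if (!x$weighted) ", unweighted", ")\n",
      "  strengths: ", format(x$observed_strengths[1]), " vs ",
      format(x$observed_strengths[2]), "; |difference| = ",
      format(x$observed_difference), "; p = ", format(x$p_value), "\n",
      sep = "")
  if (x$n_constant_events > 0)
    cat("  constant-node events in permutations:", x$n_constant_events, "\n")
  invisible(x)
}

#' Spearman correlation of edge weights between two networks
#'
#' Rank correlation over all p(p-1)/2 upper-triangle weight pairs, zeros
#' included; ties are handled by midranks. Undefined (returned as NA with an
#' explanatory attribute) when either weight vector is constant.
#'
#' @param net_a,net_b `ising_network` objects on the same node set.
#' @return Spearman rho, or NA.
#' @export
edge_weight_correlation <- function(net_a, net_b) {
  wa <- net_a$weights[upper.tri(net_a$weights)]
  wb <- net_b$weights[upper.tri(net_b$weights)]
  if (length(wa) != length(wb) || !identical(net_a$nodes, net_b$nodes))
    stop("networks must share the same node set")
  if (length(wa) < 3) stop("need at least 3 node pairs")
  if (length(unique(wa)) < 2 || length(unique(wb)) < 2) {
    out <- NA_real_
    attr(out, "reason") <- "edge-weight vector constant; rank correlation undefined"
    return(out)
  }
  stats::cor(wa, wb, method = "spearman")
}

#' Jaccard index of two networks' edge sets
#'
#' `|E_A intersect E_B| / |E_A union E_B|` over nonzero-weight edges;
#' defined as 1 when both networks are empty (identical structure).
#'
#' @param net_a,net_b `ising_network` objects on the same node set.
#' @return Value in [0, 1].
#' @export
jaccard_index <- function(net_a, net_b) {
  if (!identical(net_a$nodes, net_b$nodes))
    stop("networks must share the same node set")
  ea <- net_a$weights[upper.tri(net_a$weights)] != 0
  eb <- net_b$weights[upper.tri(net_b$weights)] != 0
  union <- sum(ea | eb)
  if (union == 0) return(1)
  sum(ea & eb) / union
}

#' All pairwise group comparisons
#'
#' Fits one network per group and computes, for every pair of groups, the
#' observed global strengths and their permutation p-value, the Spearman
#' edge-weight correlation, and the Jaccard index -- the two comparison
#' tables of a multi-group severity analysis.
#'
#' @param binary A `binary_matrix` with >= 2 groups.
#' @param n_permutations Permutations per pairwise test.
#' @param seed Master seed; each pair gets a derived child seed.
#' @param gamma,rule,n_lambda,lambda_ratio Estimator settings.
#' @param weighted Statistic on weighted (default) or unweighted networks.
#' @return A `comparison_report`: `networks` (per group), `strengths`,
#'   `comparisons` data frame (one row per pair), `rho` and `jaccard`
#'   matrices.
#' @export
pairwise_comparison_report <- function(binary, n_permutations = 10000L,
                                       seed = NULL, gamma = 0.25,
                                       rule = c("AND", "OR"),
                                       n_lambda = 100L, lambda_ratio = 0.01,
                                       weighted = TRUE) {
  rule <- match.arg(rule)
  stopifnot(inherits(binary, "binary_matrix"))
  glev <- sort(unique(binary$groups))
  K <- length(glev)
  if (K < 2) stop("need at least 2 groups")
  nets <- lapply(glev, function(g)
    fit_ising(binary$values[binary$groups == g, , drop = FALSE],
              gamma = gamma, rule = rule, n_lambda = n_lambda,
              lambda_ratio = lambda_ratio))
  names(nets) <- paste0("group", glev)
  nets <- lapply(nets, function(nt) if (weighted) nt else binarize_network(nt))
  strengths <- vapply(nets, global_strength, 0)
  pairs <- utils::combn(K, 2)
  rho <- jac <- matrix(NA_real_, K, K, dimnames = list(glev, glev))
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    nct <- nct_global_strength(
      binary$values[binary$groups == glev[i], , drop = FALSE],
      binary$values[binary$groups == glev[j], , drop = FALSE],
      n_permutations = n_permutations,
      seed = if (is.null(seed)) NULL else derive_seed(seed, 10L + k),
      gamma = gamma, rule = rule, n_lambda = n_lambda,
      lambda_ratio = lambda_ratio, weighted = weighted)
    r <- edge_weight_correlation(nets[[i]], nets[[j]])
    jc <- jaccard_index(nets[[i]], nets[[j]])
    rho[j, i] <- rho[i, j] <- as.numeric(r)
    jac[j, i] <- jac[i, j] <- jc
    rows[[k]] <- data.frame(group_a = glev[i], group_b = glev[j],
                            strength_a = nct$observed_strengths[1],
                            strength_b = nct$observed_strengths[2],
                            difference = nct$observed_difference,
                            p_value = nct$p_value,
                            spearman_rho = as.numeric(r), jaccard = jc,
                            constant_events = nct$n_constant_events)
  }
  structure(list(networks = nets, strengths = strengths,
                 comparisons = do.call(rbind, rows), rho = rho, jaccard = jac,
                 settings = list(gamma = gamma, rule = rule,
                                 n_permutations = n_permutations,
                                 weighted = weighted, seed = seed)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Pairwise network comparison report (", length(x$networks),
      " groups, ", nrow(x$comparisons), " comparisons)\n", sep = "")
  cat("Global strengths:\n")
  print(round(x$strengths, 3))
  print(x$comparisons, digits = 3)
  invisible(x)
}
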