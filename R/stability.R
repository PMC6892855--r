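# Nonparametric bootstrap of edge-weight estimation uncertainty, and the
# unweighted-network robustness re-analysis.

#' Bootstrap edge-weight confidence intervals for one group
#'
#' Resamples rows with replacement at the original n, refits the full
#' network per resample, and summarises each node pair by its percentile
#' confidence interval and selection frequency (fraction of resamples with
#' a nonzero weight). The CI comes from the bootstrap quantiles and need not
#' contain the point estimate; both are reported. Per-resample seeds are
#' derived from the master seed by counter, so results are identical
#' regardless of execution order and partial reruns are consistent.
#'
#' @param x A `binary_matrix` (single group) or 0/1 matrix.
#' @param n_boot Number of resamples (default 2500).
#' @param level Confidence level in (0, 1), default 0.95.
#' @param seed Master seed.
#' @param gamma,rule,n_lambda,lambda_ratio Estimator settings.
#' @return A `bootstrap_result`: `edges` data frame (from, to, point, lower,
#'   upper, frequency), the `boot_weights` matrix (n_boot x n_pairs), the
#'   count of resamples with constant-node drops, and the settings used.
#' @export
bootstrap_edges <- function(x, n_boot = 2500L, level = 0.95, seed = 1L,
                            gamma = 0.25, rule = c("AND", "OR"),
                            n_lambda = 100L, lambda_ratio = 0.01) {
  rule <- match.arg(rule)
  if (level <= 0 || level >= 1) stop("level: must lie in (0, 1)")
  X <- if (inherits(x, "binary_matrix")) x$values else as.matrix(x)
  n <- nrow(X); p <- ncol(X)
  nodes <- colnames(X) %||% paste0("V", seq_len(p))
  point <- fit_ising(X, gamma = gamma, rule = rule, n_lambda = n_lambda,
                     lambda_ratio = lambda_ratio)
  ut <- which(upper.tri(point$weights), arr.ind = TRUE)
  boot_w <- matrix(0, n_boot, nrow(ut))
  n_const <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, 100L, b))
    idx <- sample.int(n, n, replace = TRUE)
    fb <- fit_weights_fast(X[idx, , drop = FALSE], gamma, rule,
                           n_lambda, lambda_ratio)
    n_const <- n_const + (fb$n_dropped > 0L)
    boot_w[b, ] <- fb$weights[ut]
  }
  alpha <- (1 - level) / 2
  qs <- apply(boot_w, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  edges <- data.frame(from = nodes[ut[, 1]], to = nodes[ut[, 2]],
                      point = point$weights[ut],
                      lower = qs[1, ], upper = qs[2, ],
                      frequency = colMeans(boot_w != 0))
  structure(list(edges = edges, boot_weights = boot_w, n_boot = n_boot,
                 level = level, seed = seed,
                 n_constant_resamples = n_const, network = point),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Edge-weight bootstrap: ", x$n_boot, " resamples, ",
      100 * x$level, "% percentile CIs\n", sep = "")
  sel <- x$edges[x$edges$frequency > 0, ]
  print(sel[order(-abs(sel$point)), ], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Confidence-interval overlap summary
#'
#' For each bootstrapped network, the fraction of edge pairs whose CIs
#' overlap (a high fraction warns against over-interpreting the relative
#' ordering of edge weights), plus per-edge CI widths.
#'
#' @param results A `bootstrap_result` or list of them (one per group).
#' @param nonzero_only Restrict the pairwise overlap computation to edges
#'   present in the point-estimate network (default TRUE; absent edges all
#'   have the degenerate CI [0, 0]).
#' @return Data frame with one row per network: `n_edges`,
#'   `overlap_fraction`, `mean_ci_width`.
#' @export
ci_overlap_summary <- function(results, nonzero_only = TRUE) {
  if (inherits(results, "bootstrap_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  if (is.null(names(results)))
    names(results) <- paste0("group", seq_along(results))
  rows <- lapply(names(results), function(nm) {
    e <- results[[nm]]$edges
    if (nonzero_only) e <- e[e$point != 0, ]
    ov <- NA_real_
    if (nrow(e) >= 2) {
      pr <- utils::combn(nrow(e), 2)
      ov <- mean(e$lower[pr[1, ]] <= e$upper[pr[2, ]] &
                 e$lower[pr[2, ]] <= e$upper[pr[1, ]])
    }
    data.frame(group = nm, n_edges = nrow(e), overlap_fraction = ov,
               mean_ci_width = if (nrow(e)) mean(e$upper - e$lower) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Unweighted-network robustness re-analysis
#'
#' Repeats the structural analyses using only edge presence/absence:
#' global strength becomes the edge count, the permutation comparison test
#' uses the edge-count statistic, Jaccard indices are recomputed, and
#' community detection runs on the binarized networks. Emitted side by side
#' with the weighted results so conclusions can be checked against
#' edge-weight estimation uncertainty.
#'
#' @param binary A `binary_matrix` with >= 2 groups.
#' @param weighted_report The `comparison_report` from the weighted
#'   analysis (its settings are reused).
#' @param n_permutations Permutations for the unweighted comparison test
#'   (defaults to the weighted report's setting).
#' @param seed Seed for the unweighted permutation stream.
#' @return A `robustness_report`: unweighted `report`, unweighted
#'   `partitions` (walktrap), and a `side_by_side` strength/Q table.
#' @export
robustness_reanalysis <- function(binary, weighted_report,
                                  n_permutations = NULL, seed = NULL) {
  stopifnot(inherits(binary, "binary_matrix"),
            inherits(weighted_report, "comparison_report"))
  s <- weighted_report$settings
  if (is.null(n_permutations)) n_permutations <- s$n_permutations
  if (is.null(seed)) seed <- s$seed
  unw <- pairwise_comparison_report(binary, n_permutations = n_permutations,
                                    seed = seed, gamma = s$gamma,
                                    rule = s$rule, weighted = FALSE)
  parts_w <- lapply(weighted_report$networks, walktrap_communities)
  parts_u <- lapply(unw$networks, walktrap_communities)
  side <- data.frame(
    group = names(weighted_report$networks),
    strength_weighted = unname(weighted_report$strengths),
    strength_unweighted = unname(unw$strengths),
    q_weighted = vapply(parts_w, function(p) p$modularity_Q, 0),
    q_unweighted = vapply(parts_u, function(p) p$modularity_Q, 0),
    row.names = NULL)
  structure(list(report = unw, partitions = parts_u, side_by_side = side),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Unweighted robustness re-analysis\n")
  print(x$side_by_side, digits = 3)
  invisible(x)
}
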