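# Regularised Ising network estimation (eLasso): nodewise L1-penalised
# logistic regressions with EBIC lambda selection, symmetrised by the
# AND/OR rule. State coding is {0,1} throughout.

#' Data-driven lambda sequence for a penalised logistic regression
#'
#' Log-spaced from `lambda_max` -- the smallest per-observation penalty at
#' which every coefficient is zero, `max_j |x_j'(y - mean(y))| / n` by the
#' KKT condition at the intercept-only fit -- down to
#' `lambda_ratio * lambda_max`.
#'
#' @param y Binary response vector.
#' @param X Predictor matrix.
#' @param n_lambda Number of grid points (>= 2).
#' @param lambda_ratio Ratio of smallest to largest lambda, in (0, 1).
#' @return Decreasing numeric vector of length `n_lambda`.
#' @export
lambda_sequence <- function(y, X, n_lambda = 100L, lambda_ratio = 0.01) {
  if (n_lambda < 2) stop("n_lambda: must be >= 2")
  if (lambda_ratio <= 0 || lambda_ratio >= 1)
    stop("lambda_ratio: must lie in (0, 1)")
  X <- as.matrix(X)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / length(y)
  if (lmax <= 0) lmax <- 1e-4
  exp(seq(log(lmax), log(lmax * lambda_ratio), length.out = n_lambda))
}

#' L1-penalised logistic regression path
#'
#' Minimises, for each lambda on the path,
#' `(1/n) sum_i [log(1 + exp(eta_i)) - y_i eta_i] + lambda * sum_j |beta_j|`
#' with an unpenalised intercept, by iteratively reweighted least squares
#' with cyclic coordinate descent and warm starts. Convergence is declared
#' when no coefficient moves by more than `tol`; non-convergence is an error
#' naming the lambda index. Following standard pathwise practice, the path
#' stops early once the fractional deviance-explained gain per step falls
#' below 1e-5, so the returned path may be shorter than the requested grid.
#'
#' @param y Binary 0/1 response; must not be constant.
#' @param X Predictor matrix; columns must not be constant.
#' @param lambdas Optional decreasing penalty sequence; defaults to
#'   [lambda_sequence()].
#' @param n_lambda,lambda_ratio Grid parameters when `lambdas` is NULL.
#' @param tol Convergence tolerance on coefficient change.
#' @param max_iter Maximum reweighting iterations per lambda.
#' @return A `lasso_path`: `lambdas`, `beta` (p x n_lambda), `intercepts`,
#'   `loglik`, `df` (nonzero counts).
#' @export
logistic_lasso_path <- function(y, X, lambdas = NULL, n_lambda = 100L,
                                lambda_ratio = 0.01, tol = 1e-7,
                                max_iter = 200L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(y) || anyNA(X)) stop("missing values are not allowed")
  if (length(unique(y)) < 2)
    stop("y is constant; a degenerate node must be filtered before fitting")
  if (any(apply(X, 2, function(v) length(unique(v)) < 2)))
    stop("X contains constant column(s)")
  if (is.null(lambdas)) lambdas <- lambda_sequence(y, X, n_lambda, lambda_ratio)
  fit <- lasso_path_cpp(y, X, as.numeric(lambdas), tol, as.integer(max_iter))
  u <- seq_len(fit$n_used)  # the path stops early once deviance gain stalls
  structure(list(lambdas = as.numeric(lambdas)[u],
                 beta = fit$beta[, u, drop = FALSE],
                 intercepts = fit$intercepts[u], loglik = fit$loglik[u],
                 df = fit$df[u]),
            class = "lasso_path")
}

#' Extended Bayesian information criterion
#'
#' `EBIC = -2 loglik + k log(n) + 2 gamma k log(P)` where k is the number of
#' nonzero coefficients and P the number of candidate predictors. `gamma = 0`
#' recovers the ordinary BIC; larger gamma penalises model size more heavily,
#' which is what makes the nodewise Ising estimator conservative.
#'
#' @param loglik Fitted log-likelihood.
#' @param k_nonzero Number of nonzero (penalised) coefficients.
#' @param n Sample size.
#' @param n_candidates Number of candidate predictors P.
#' @param gamma EBIC hyperparameter, >= 0.
#' @return The EBIC value.
#' @export
ebic <- function(loglik, k_nonzero, n, n_candidates, gamma) {
  if (any(n < 1)) stop("n: must be >= 1")
  if (any(k_nonzero < 0)) stop("k_nonzero: must be >= 0")
  if (any(gamma < 0)) stop("gamma: must be >= 0")
  -2 * loglik + k_nonzero * log(n) + 2 * gamma * k_nonzero * log(n_candidates)
}

#' Fit a regularised Ising network to one group's binary data
#'
#' For every node j, an L1-penalised logistic regression of node j on all
#' other nodes is fitted along a data-driven lambda path, and the penalty is
#' selected by EBIC with `P = p - 1` candidates. An edge (i, j) is included
#' under the AND rule iff both directed coefficients are nonzero (OR rule:
#' either), and its weight is the arithmetic mean of the two coefficients;
#' absent edges have weight exactly 0.
#'
#' @param x A `binary_matrix` (single group) or plain 0/1 matrix.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param rule Edge-inclusion rule, `"AND"` (default) or `"OR"`.
#' @param n_lambda,lambda_ratio Lambda path settings (defaults 100 and 0.01).
#' @param on_constant What to do with nodes constant in this sample:
#'   `"drop"` (default) drops them with a warning and reports them isolated;
#'   `"error"` aborts listing the offending nodes.
#' @param tol,max_iter Solver settings.
#' @return An `ising_network`: symmetric `weights` (zero diagonal),
#'   `intercepts`, `nodes`, `dropped`, `n_fit`, `gamma`, `rule`.
#' @export
fit_ising <- function(x, gamma = 0.25, rule = c("AND", "OR"),
                      n_lambda = 100L, lambda_ratio = 0.01,
                      on_constant = c("drop", "error"),
                      tol = 1e-7, max_iter = 200L) {
  rule <- match.arg(rule)
  on_constant <- match.arg(on_constant)
  X <- if (inherits(x, "binary_matrix")) x$values else as.matrix(x)
  if (anyNA(X)) stop("missing values are not allowed")
  p <- ncol(X)
  if (p < 2) stop("need at least 2 nodes")
  nodes <- colnames(X) %||% paste0("V", seq_len(p))
  const <- vapply(seq_len(p), function(j) length(unique(X[, j])) < 2,
                  logical(1))
  if (any(const)) {
    if (on_constant == "error")
      stop("constant node(s) in this group, drop before fitting: ",
           paste(nodes[const], collapse = ", "))
    warning("dropping constant node(s), reported as isolated: ",
            paste(nodes[const], collapse = ", "))
  }
  keep <- which(!const)
  if (nrow(X) < p)
    warning("fewer observations (", nrow(X), ") than nodes (", p, ")")
  W <- matrix(0, p, p, dimnames = list(nodes, nodes))
  intercepts <- stats::setNames(rep(NA_real_, p), nodes)
  if (length(keep) >= 2) {
    fit <- elasso_nodewise_cpp(matrix(as.numeric(X[, keep]), nrow(X)),
                               gamma, as.integer(n_lambda), lambda_ratio,
                               tol, as.integer(max_iter))
    B <- fit$directed  # B[i, j]: coefficient of node i in node j's regression
    present <- if (rule == "AND") (B != 0) & (t(B) != 0)
               else (B != 0) | (t(B) != 0)
    Wk <- ifelse(present, (B + t(B)) / 2, 0)
    diag(Wk) <- 0
    W[keep, keep] <- Wk
    intercepts[keep] <- fit$intercepts
  }
  structure(list(weights = W, intercepts = intercepts, nodes = nodes,
                 dropped = nodes[const], n_fit = nrow(X), gamma = gamma,
                 rule = rule, weighted = TRUE),
            class = "ising_network")
}

#' @export
print.ising_network <- function(x, ...) {
  ut <- x$weights[upper.tri(x$weights)]
  cat("Ising network: ", length(x$nodes), " nodes, ", sum(ut != 0),
      " edges (rule = ", x$rule, ", gamma = ", x$gamma, ", n = ", x$n_fit,
      ")\nGlobal strength: ", format(global_strength(x)), "\n", sep = "")
  if (length(x$dropped))
    cat("Dropped constant nodes:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Global network strength
#'
#' The absolute sum of all edge weights over unique node pairs; a scalar
#' summary of the total unique covariation in the network. For an unweighted
#' network this is simply the edge count.
#'
#' @param net An `ising_network` (or a symmetric weight matrix).
#' @return Non-negative scalar.
#' @export
global_strength <- function(net) {
  W <- if (inherits(net, "ising_network")) net$weights else as.matrix(net)
  sum(abs(W[upper.tri(W)]))
}

#' Reduce a network to unweighted presence/absence form
#'
#' Every nonzero edge weight becomes 1, used for the robustness re-analysis
#' in which all statistics are recomputed on edge presence alone.
#'
#' @param net An `ising_network`.
#' @return An `ising_network` with 0/1 weights and `weighted = FALSE`.
#' @export
binarize_network <- function(net) {
  stopifnot(inherits(net, "ising_network"))
  net$weights <- (net$weights != 0) + 0
  net$weighted <- FALSE
  net
}

#' Edge list of a network
#'
#' @param net An `ising_network`.
#' @param all Include absent (zero-weight) pairs?
#' @return Data frame with columns `from`, `to`, `weight`.
#' @export
edge_list <- function(net, all = FALSE) {
  W <- net$weights
  idx <- which(upper.tri(W), arr.ind = TRUE)
  out <- data.frame(from = net$nodes[idx[, 1]], to = net$nodes[idx[, 2]],
                    weight = W[idx])
  if (!all) out <- out[out$weight != 0, ]
  rownames(out) <- NULL
  out
}
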