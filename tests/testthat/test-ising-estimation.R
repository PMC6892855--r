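# Nodewise eLasso estimation: solver oracles, EBIC, and network assembly.

test_that("EBIC reduces to its closed forms", {
  # gamma = 0: ordinary BIC
  expect_equal(ebic(-50, 2, 200, 5, 0), 100 + 2 * log(200))
  # k = 0: -2 loglik exactly
  expect_equal(ebic(-123.4, 0, 50, 10, 0.5), 246.8)
  # direct evaluation
  expect_equal(ebic(-100, 3, 100, 10, 0.25),
               200 + 3 * log(100) + 1.5 * log(10), tolerance = 1e-12)
  expect_error(ebic(-1, -1, 10, 3, 0.25), "k_nonzero")
  expect_error(ebic(-1, 1, 10, 3, -0.1), "gamma")
})

test_that("lambda sequence is log-spaced from the data-derived maximum", {
  set.seed(3)
  X <- matrix(rbinom(300, 1, 0.5), 100, 3)
  y <- rbinom(100, 1, 0.5)
  lam <- lambda_sequence(y, X, n_lambda = 25, lambda_ratio = 0.02)
  expect_length(lam, 25)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / 100
  expect_equal(lam[1], lmax)
  expect_equal(lam[25], 0.02 * lmax)
  expect_equal(diff(log(lam)), rep(diff(log(lam))[1], 24), tolerance = 1e-12)
  # the first element zeroes every coefficient
  path <- logistic_lasso_path(y, X, lambdas = lam)
  expect_true(all(path$beta[, 1] == 0))
  expect_error(lambda_sequence(y, X, n_lambda = 1), "n_lambda")
  expect_error(lambda_sequence(y, X, lambda_ratio = 1), "lambda_ratio")
})

test_that("the penalised solver matches independent oracles", {
  set.seed(7)
  X <- matrix(rbinom(600, 1, 0.5), 200, 3)
  y <- rbinom(200, 1, stats::plogis(-0.5 + X %*% c(1, -0.8, 0)))
  # lambda -> 0: unpenalised MLE from R's IRLS
  path <- logistic_lasso_path(y, X, lambdas = c(0.3, 1e-9))
  fit <- stats::glm(y ~ X, family = binomial)
  expect_equal(unname(path$beta[, 2]), unname(coef(fit)[2:4]),
               tolerance = 1e-6)
  expect_equal(path$intercepts[2], unname(coef(fit)[1]), tolerance = 1e-6)
  # loglik bookkeeping agrees with direct evaluation
  eta <- path$intercepts[2] + X %*% path$beta[, 2]
  expect_equal(path$loglik[2], sum(y * eta - log1p(exp(eta))),
               tolerance = 1e-8)

  # mid-path shrunk coefficients against glmnet at matched penalties
  lam <- lambda_sequence(y, X)[c(10, 40, 80)]
  gn <- glmnet::glmnet(X, y, family = "binomial", lambda = lam,
                       standardize = FALSE, thresh = 1e-12)
  mine <- logistic_lasso_path(y, X, lambdas = lam)
  expect_equal(unname(mine$beta), unname(as.matrix(gn$beta)),
               tolerance = 1e-5)

  expect_error(logistic_lasso_path(rep(1, 200), X), "constant")
  expect_error(logistic_lasso_path(y, cbind(X, 0)), "constant column")
})

test_that("duplicating every observation leaves the path unchanged", {
  set.seed(19)
  X <- matrix(rbinom(400, 1, 0.5), 100, 4)
  y <- rbinom(100, 1, stats::plogis(X %*% c(1, -1, 0, 0)))
  lam <- lambda_sequence(y, X, n_lambda = 10)
  p1 <- logistic_lasso_path(y, X, lambdas = lam)
  # lambda is per-observation, so the duplicated problem uses the same grid
  p2 <- logistic_lasso_path(rep(y, 2), rbind(X, X), lambdas = lam)
  expect_equal(p1$beta, p2$beta, tolerance = 1e-6)
  expect_equal(2 * p1$loglik, p2$loglik, tolerance = 1e-6)
})

test_that("nonzero count is non-increasing in lambda along fixture paths", {
  set.seed(23)
  for (r in 1:5) {
    X <- sample_ising_exact(chain_network(5), 400, seed = 700 + r)
    path <- logistic_lasso_path(X[, 1], X[, -1])
    expect_true(all(diff(path$df) >= 0))  # lambdas decrease along the path
  }
})

test_that("fit_ising output is symmetric, named and relabeling-equivariant", {
  X <- sample_ising_exact(chain_network(5), 800, seed = 62)
  colnames(X) <- LETTERS[1:5]
  f <- fit_ising(X)
  expect_equal(f$weights, t(f$weights))
  expect_true(all(diag(f$weights) == 0))
  perm <- c(3, 1, 5, 2, 4)
  fp <- fit_ising(X[, perm])
  # equal up to solver tolerance: node order changes the sweep order
  expect_equal(fp$weights, f$weights[perm, perm], tolerance = 1e-6)
  expect_identical(fp$weights != 0, f$weights[perm, perm] != 0)
})

test_that("EBIC-selected network is invariant to row order", {
  X <- sample_ising_exact(chain_network(5), 500, seed = 15)
  f1 <- fit_ising(X)
  set.seed(1)
  f2 <- fit_ising(X[sample(nrow(X)), ])
  expect_equal(f1$weights, f2$weights)
})

test_that("the AND-rule edge set is a subset of the OR-rule edge set", {
  for (r in 1:5) {
    X <- sample_ising_exact(chain_network(6, coupling = 0.8), 300,
                            seed = 880 + r)
    e_and <- fit_ising(X, rule = "AND")$weights != 0
    e_or <- fit_ising(X, rule = "OR")$weights != 0
    expect_true(all(e_or[e_and]))
  }
})

test_that("constant nodes are dropped with a warning (or error on request)", {
  X <- sample_ising_exact(chain_network(4), 300, seed = 5)
  X <- cbind(X, DEAD = 0L)
  expect_warning(f <- fit_ising(X), "DEAD")
  expect_equal(f$dropped, "DEAD")
  expect_true(all(f$weights[, "DEAD"] == 0))
  expect_error(fit_ising(X, on_constant = "error"), "DEAD")
  tiny <- rbind(c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L), c(1L, 1L, 0L, 0L))
  expect_warning(fit_ising(tiny), "fewer observations")
})

test_that("nodewise logistic coefficients converge to the conditional truth", {
  # For an Ising model, logit P(x_i = 1 | rest) has coefficients beta_i.
  # and intercept tau_i; unpenalised nodewise fits must approach them.
  net <- chain_network(4, coupling = 1.2, threshold = -0.6)
  err <- numeric(2)
  for (k in 1:2) {
    n <- c(5000, 20000)[k]
    X <- sample_ising_exact(net, n, seed = 31 + k)
    fit <- stats::glm(X[, 2] ~ X[, -2], family = binomial)
    est <- unname(coef(fit))
    tru <- c(net$thresholds[2], net$couplings[2, -2])
    err[k] <- max(abs(est - tru))
  }
  expect_lt(err[2], err[1])   # bias and noise shrink with n
  expect_lt(err[2], 0.15)
})

test_that("global strength and network binarization behave as defined", {
  W <- matrix(0, 4, 4)
  net <- as_ising_net(W)
  expect_equal(global_strength(net), 0)
  W[1, 2] <- W[2, 1] <- 0.7
  expect_equal(global_strength(as_ising_net(W)), 0.7)
  W[1, 3] <- W[3, 1] <- -0.3
  W[2, 4] <- W[4, 2] <- 0.5
  W[3, 4] <- W[4, 3] <- 0.2
  net <- as_ising_net(W)
  expect_equal(global_strength(net), 1.7)
  # invariance under relabeling and sign flips
  perm <- c(4, 2, 1, 3)
  expect_equal(global_strength(as_ising_net(W[perm, perm])), 1.7)
  W2 <- W
  W2[1, 3] <- W2[3, 1] <- 0.3
  expect_equal(global_strength(as_ising_net(W2)), 1.7)

  b <- binarize_network(net)
  expect_true(all(b$weights %in% c(0, 1)))
  expect_equal(b$weights != 0, net$weights != 0)
  expect_equal(binarize_network(b)$weights, b$weights)  # idempotent
  expect_equal(global_strength(b), 4)  # edge count
  empty <- binarize_network(as_ising_net(matrix(0, 3, 3)))
  expect_true(all(empty$weights == 0))
})
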