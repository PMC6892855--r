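# Prevalence-matched severity thresholds and variance diagnostics.

# brute-force oracle: best integer cutoff for one group/domain
oracle_cutoff <- function(scores, target) {
  cand <- seq_len(max(scores))
  prev <- vapply(cand, function(c) mean(scores >= c), 0)
  best <- which(abs(prev - target) == min(abs(prev - target)))[1]
  c(cutoff = cand[best], prev = prev[best])
}

test_that("fitted cutoff minimises the prevalence deviation (brute force)", {
  scores <- c(0, 0, 1, 2, 3, 3, 4, 5, 6, 8)
  orc <- oracle_cutoff(scores, 0.30)
  sch <- fit_thresholds(matrix(scores, ncol = 1), rep(1, 10),
                        target_prevalences = 0.30)
  expect_equal(unname(sch$cutoffs[1, 1]), unname(orc["cutoff"]))
  expect_equal(unname(sch$achieved[1, 1]), unname(orc["prev"]))
  expect_equal(unname(sch$achieved[1, 1]), 0.30)

  # randomised cases against the same oracle, two groups
  set.seed(21)
  for (r in 1:10) {
    s <- matrix(rpois(120, 3), 60, 2)
    g <- rep(1:2, each = 30)
    tgt <- runif(1, 0.2, 0.6)
    sch <- fit_thresholds(s, g, target_prevalences = tgt)
    for (gi in 1:2) for (d in 1:2) {
      orc <- oracle_cutoff(s[g == gi, d], tgt)
      expect_equal(unname(sch$cutoffs[gi, d]), unname(orc["cutoff"]))
    }
  }
})

test_that("thresholds are shift-equivariant across groups", {
  set.seed(13)
  a <- rpois(200, 2)
  scores <- matrix(c(a, a + 2L), ncol = 1)
  g <- rep(1:2, each = 200)
  sch <- fit_thresholds(scores, g, target_prevalences = 0.4)
  expect_equal(unname(sch$cutoffs[2, 1]), unname(sch$cutoffs[1, 1]) + 2)
  bin <- apply_thresholds(scores, g, sch)
  expect_identical(bin$values[g == 1, 1], bin$values[g == 2, 1])
})

test_that("target 0.5 on a symmetric sample is achieved within one observation", {
  s <- matrix(c(0:9), ncol = 1)  # symmetric around its median
  sch <- fit_thresholds(s, rep(1, 10), target_prevalences = 0.5)
  expect_lte(abs(sch$achieved[1, 1] - 0.5), 1 / 10)
})

test_that("constant domains and missing scores are rejected", {
  s <- matrix(c(rep(1L, 10), 0:9), ncol = 2)
  expect_error(fit_thresholds(s, rep(1, 10)), "constant within group")
  s2 <- matrix(c(0:9), ncol = 1)
  sch <- fit_thresholds(s2, rep(1, 10), target_prevalences = 0.4)
  s2[3] <- NA
  expect_error(apply_thresholds(s2, rep(1, 10), sch), "missing")
})

test_that("apply_thresholds matches elementwise comparison and flags degenerate columns", {
  set.seed(31)
  s <- matrix(rpois(300, 3), 100, 3)
  g <- rep(1:2, each = 50)
  sch <- fit_thresholds(s, g, target_prevalences = c(0.3, 0.5, 0.7))
  bin <- apply_thresholds(s, g, sch)
  oracle <- matrix(0L, 100, 3)
  for (i in 1:100) for (d in 1:3)
    oracle[i, d] <- as.integer(s[i, d] >= sch$cutoffs[g[i], d])
  expect_equal(unname(bin$values), oracle)
  # cutoff 1 is exactly score > 0
  sch$cutoffs[] <- 1
  bin1 <- apply_thresholds(s, g, sch)
  expect_equal(unname(bin1$values), unname((s > 0) + 0L))
  # cutoff above the max score: all-zero column, flagged as constant
  sch$cutoffs[] <- max(s) + 1L
  bin0 <- apply_thresholds(s, g, sch)
  expect_true(all(bin0$values == 0))
  expect_gt(nrow(bin0$constant_cells), 0)
})

test_that("binarization is monotone in the underlying score", {
  set.seed(77)
  s <- matrix(rpois(100, 3), 50, 2)
  g <- rep(1:2, each = 25)
  sch <- fit_thresholds(s, g, target_prevalences = 0.4)
  before <- apply_thresholds(s, g, sch)$values
  s2 <- s
  s2[8, 1] <- s2[8, 1] + 3L  # raise one individual's score
  after <- apply_thresholds(s2, g, sch)$values
  expect_true(all(after >= before))
})

test_that("prevalence_table reports within-group column means", {
  v <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0), 4)
  b <- sevnet:::binary_matrix(v, rep(1, 4))
  pt <- prevalence_table(b)
  expect_equal(unname(pt[1, ]), c(1, 0.5))
  v2 <- rbind(v, v)
  b2 <- sevnet:::binary_matrix(v2, rep(1:2, each = 4))
  expect_equal(unname(prevalence_table(b2)[1, ]),
               unname(prevalence_table(b2)[2, ]))
})

test_that("Brown-Forsythe test matches its oracle and detects unequal variance", {
  # identical columns duplicated into two groups: statistic 0, p = 1
  v <- matrix(rep(c(1L, 0L, 1L, 1L, 0L), 2), ncol = 1)
  b <- sevnet:::binary_matrix(v, rep(1:2, each = 5))
  res <- variance_equality_test(b)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # agreement with car::leveneTest(center = median) on a random fixture
  set.seed(55)
  x <- c(rbinom(40, 1, 0.3), rbinom(40, 1, 0.45))
  g <- rep(1:2, each = 40)
  b2 <- sevnet:::binary_matrix(matrix(x, ncol = 1), g)
  mine <- variance_equality_test(b2)
  lev <- car::leveneTest(x ~ factor(g), center = median)
  expect_equal(mine$statistic, lev$`F value`[1], tolerance = 1e-12)
  expect_equal(mine$p_value, lev$`Pr(>F)`[1], tolerance = 1e-12)

  # prevalence 0.5 vs 0.9 at n = 500: variances differ, test rejects
  set.seed(56)
  x3 <- c(rbinom(500, 1, 0.5), rbinom(500, 1, 0.9))
  b3 <- sevnet:::binary_matrix(matrix(x3, ncol = 1), rep(1:2, each = 500))
  expect_lt(variance_equality_test(b3)$p_value, 0.05)

  expect_error(variance_equality_test(b3[["values"]]), "binary_matrix")
})

test_that("cutoffs are non-decreasing in severity for shifted groups", {
  co <- generate_ordinal_cohort(cohort_spec(group_sizes = rep(250L, 4),
                                            seed = 17))
  sch <- fit_thresholds(co$domain_scores, co$group_labels)
  expect_true(all(apply(sch$cutoffs, 2, function(cc) all(diff(cc) >= 0))))
  # cross-group prevalence range within the discreteness bound
  bin <- apply_thresholds(co$domain_scores, co$group_labels, sch)
  rng <- attr(prevalence_table(bin), "range")
  bound <- prevalence_discreteness_bound(co$domain_scores, co$group_labels,
                                         sch)
  expect_true(all(rng <= bound + 1e-12))
})
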