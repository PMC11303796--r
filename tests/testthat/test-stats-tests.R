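test_that("Hotelling T2 reduces exactly to the squared t statistic when L = 1", {
  set.seed(1)
  for (i in 1:100) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    x <- matrix(rnorm(n1), ncol = 1)
    y <- matrix(rnorm(n2, mean = runif(1, -1, 1)), ncol = 1)
    ht <- hotelling_t2(x, y)
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ht$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(ht$p.value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Hotelling T2 matches direct matrix-formula evaluation", {
  # 3 + 3 subjects, L = 2, small integer data; oracle = explicit 2x2 inverse
  x <- matrix(c(1, 2, 3, 2, 4, 3), 3, 2)
  y <- matrix(c(4, 5, 7, 1, 2, 2), 3, 2)
  d <- colMeans(x) - colMeans(y)
  S <- (2 * cov(x) + 2 * cov(y)) / 4
  det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
  Sinv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2) / det_s
  t2_oracle <- (3 * 3 / 6) * as.numeric(t(d) %*% Sinv %*% d)
  ht <- hotelling_t2(x, y)
  expect_equal(ht$statistic, t2_oracle, tolerance = 1e-12)
  expect_equal(ht$f, t2_oracle * (6 - 2 - 1) / (2 * (6 - 2)), tolerance = 1e-12)
})

test_that("identical group means give near-zero T2 and p near 1", {
  set.seed(9)
  base <- matrix(rep(c(2, 5), each = 4), 4, 2)
  ht <- hotelling_t2(base + 1e-4 * matrix(rnorm(8), 4, 2),
                     base + 1e-4 * matrix(rnorm(8), 4, 2))
  expect_lt(ht$statistic, 20)           # O(1) statistic despite epsilon scale
  expect_gt(ht$p.value, 0.2)
  expect_error(hotelling_t2(matrix(1:2, 2, 2), matrix(1:2, 1, 2)), "n1 \\+ n2")
})

test_that("node-wise Hotelling engine agrees with the reference test", {
  set.seed(7)
  for (L in 1:3) {
    scores <- array(rnorm(20 * 10 * L), c(20, 10, L))
    g <- rep(c(TRUE, FALSE), each = 10)
    nh <- alongtract:::node_hotelling(alongtract:::split_score_layers(scores), g)
    for (k in c(1, 5, 10)) {
      ref <- hotelling_t2(scores[g, k, , drop = FALSE][, 1, ],
                          scores[!g, k, , drop = FALSE][, 1, ])
      expect_equal(nh$t2[k], ref$statistic, tolerance = 1e-10)
      expect_equal(nh$p[k], ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("group test returns zero T2 on byte-identical groups", {
  set.seed(2)
  half <- array(rnorm(5 * 8 * 2), c(5, 8, 2))
  scores <- array(0, c(10, 8, 2))
  scores[1:5, , ] <- half
  scores[6:10, , ] <- half
  g <- rep(c(TRUE, FALSE), each = 5)
  out <- group_test_along_tract(scores, g)
  expect_true(all(out$statistic < 1e-18))
  expect_true(all(abs(out[[paste0("d_PC", 1)]]) < 1e-9))
  expect_error(group_test_along_tract(scores, rep(c(TRUE, FALSE), c(2, 8))),
               "at least 3")
})

test_that("Cohen's d is the standardized mean difference per component", {
  set.seed(3)
  scores <- array(rnorm(30 * 4 * 1), c(30, 4, 1))
  g <- rep(c(TRUE, FALSE), each = 15)
  scores[g, , 1] <- scores[g, , 1] + 1
  out <- group_test_along_tract(scores, g)
  for (k in 1:4) {
    x <- scores[g, k, 1]; y <- scores[!g, k, 1]
    sp <- sqrt(((14) * var(x) + (14) * var(y)) / 28)
    expect_equal(out$d_PC1[k], (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  }
})

test_that("perfect association gives p ~ 0 and |r| ~ 1 at the node", {
  set.seed(4)
  n <- 25
  scores <- array(rnorm(n * 6 * 1), c(n, 6, 1))
  aes <- 3 * scores[, 4, 1]               # exact linear function of PC1 at node 4
  out <- association_along_tract(scores, aes)
  expect_lt(out$p.value[4], 1e-12)
  expect_equal(out$r[4], 1, tolerance = 1e-9)
  expect_gt(min(out$p.value[-4]), 1e-6)
})

test_that("association p-values are uniform under the null", {
  # KS test pooled over 100 null simulations, not rejected at 1%
  set.seed(5)
  pvals <- unlist(lapply(1:100, function(i) {
    scores <- array(rnorm(30 * 10 * 2), c(30, 10, 2))
    aes <- rnorm(30)
    association_along_tract(scores, aes)$p.value
  }))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("association effect sign follows the dominant component", {
  set.seed(6)
  n <- 35
  scores <- array(rnorm(n * 8 * 2), c(n, 8, 2))
  aes <- -2 * scores[, 3, 1] + rnorm(n, sd = 0.5)
  out <- association_along_tract(scores, aes)
  expect_lt(out$r[3], 0)
  expect_lt(out$r_PC1[3], 0)
})

test_that("chi-squared contingency test matches its closed form", {
  # demographics worked example: 9:26 males vs 5:16
  demo <- contingency_chi2(matrix(c(9, 5, 26, 16), 2, byrow = FALSE))
  expect_equal(round(demo$statistic, 2), 0.03)
  expect_gt(demo$p.value, 0.8)

  # proportional table has statistic exactly 0
  expect_equal(contingency_chi2(matrix(c(10, 5, 20, 10), 2))$statistic, 0,
               tolerance = 1e-12)

  # oracle: direct expected-count summation for a diagonal table
  tab <- matrix(c(20, 0, 0, 20), 2)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  oracle <- sum((tab - exp_counts)^2 / exp_counts)
  expect_equal(oracle, 40)
  expect_equal(contingency_chi2(tab)$statistic, 40, tolerance = 1e-12)

  expect_error(contingency_chi2(matrix(c(0, 0, 5, 6), 2)), "margin")
  expect_error(contingency_chi2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})
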