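test_that("pruning removes the right member of over-correlated pairs", {
  # exact correlations: A~B 0.90, A~C 0.85, B~C 0.55 -> A has the largest
  # mean |r| and is removed; the B~C pair is below threshold and survives
  R <- matrix(c(1, .90, .85,
                .90, 1, .55,
                .85, .55, 1), 3, 3)
  X <- make_exact_cor_data(20 * 50, R, seed = 4)
  arr <- array(X, c(20, 50, 3))
  prof <- array_to_profiles(arr, c("A", "B", "C"))
  pr <- prune_correlated(prof, 0.8)
  expect_identical(sort(pr$retained), c("B", "C"))
  expect_identical(pr$removed, "A")
  # final retained matrix has no violation (oracle check)
  sub <- abs(pr$cor_matrix[pr$retained, pr$retained])
  diag(sub) <- 0
  expect_true(all(sub <= 0.8))

  # a single pair above threshold drops one member
  R2 <- matrix(c(1, .9, .9, 1), 2)
  prof2 <- array_to_profiles(array(make_exact_cor_data(600, R2), c(12, 50, 2)),
                             c("A", "B"))
  pr2 <- prune_correlated(prof2)
  expect_length(pr2$retained, 1)

  # all pairwise r <= 0.8 is a no-op
  R3 <- diag(3) * 0.5 + 0.5 * matrix(0.4, 3, 3); diag(R3) <- 1
  prof3 <- array_to_profiles(array(make_exact_cor_data(600, R3), c(12, 50, 3)),
                             c("A", "B", "C"))
  expect_length(prune_correlated(prof3)$retained, 3)
})

test_that("PCA keeps the smallest L reaching the variance target", {
  # rank-1 data: two perfectly correlated metrics
  set.seed(11)
  base <- matrix(rnorm(500), 10, 50)
  arr <- array(c(base, 2 * base), c(10, 50, 2))
  pc <- fit_pca(array_to_profiles(arr, c("A", "B")))
  expect_identical(pc$L, 1L)
  expect_equal(pc$explained_variance_ratio[1], 1, tolerance = 1e-9)

  # single metric
  pc1 <- fit_pca(array_to_profiles(array(base, c(10, 50, 1)), "A"))
  expect_identical(pc1$L, 1L)
})

test_that("PCA recovers a planted two-factor structure", {
  # 5 metrics from 2 latent factors carrying ~70% / ~25% of the variance
  load1 <- c(0.9, 0.85, 0.8, 0.9, 0.85) * sqrt(0.70) / 0.86
  load2 <- c(0.5, -0.5, 0.55, -0.45, 0.5) * sqrt(0.25) / 0.50
  ratios <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 30; nn <- 60
    f1 <- matrix(rnorm(n * nn), n, nn)
    f2 <- matrix(rnorm(n * nn), n, nn)
    arr <- array(NA_real_, c(n, nn, 5))
    for (m in 1:5) {
      arr[, , m] <- load1[m] * f1 + load2[m] * f2 +
        sqrt(max(1 - load1[m]^2 - load2[m]^2, 0.02)) * matrix(rnorm(n * nn), n, nn)
    }
    pc <- fit_pca(array_to_profiles(arr, paste0("m", 1:5)))
    c(L = pc$L, r1 = pc$explained_variance_ratio[1],
      r2 = pc$explained_variance_ratio[2])
  }, numeric(3))
  expect_true(all(ratios["L", ] == 2))
  expect_equal(mean(ratios["r1", ]), 0.70, tolerance = 0.05)
  expect_equal(mean(ratios["r2", ]), 0.25, tolerance = 0.05)
})

test_that("PCA loadings are orthonormal with non-increasing variance ratios", {
  sim <- gen_profiles(profile_sim_spec(seed = 21))
  pc <- fit_pca(sim$profiles)
  G <- t(pc$loadings) %*% pc$loadings
  expect_equal(G, diag(pc$L), tolerance = 1e-12, ignore_attr = TRUE)
  evr <- pc$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_lte(sum(evr), 1 + 1e-12)
  # sign anchor: FW loading non-negative where appreciable
  if ("FW" %in% rownames(pc$loadings)) {
    fw <- pc$loadings["FW", ]
    expect_true(all(fw[abs(fw) >= 0.1] > 0))
  }
})

test_that("zero-variance metrics are dropped with a warning", {
  set.seed(3)
  arr <- array(c(matrix(rnorm(500), 10, 50), matrix(1, 10, 50)), c(10, 50, 2))
  expect_warning(pc <- fit_pca(array_to_profiles(arr, c("A", "B"))),
                 "zero-variance")
  expect_identical(pc$metrics, "A")
})

test_that("residualization leaves scores orthogonal to every covariate", {
  set.seed(8)
  n <- 40
  meta <- simple_meta(n, seed = 8)
  scores <- array(rnorm(n * 30 * 2), c(n, 30, 2),
                  dimnames = list(meta$subject, 1:30, c("PC1", "PC2")))
  # plant a strong age slope
  scores[, , 1] <- scores[, , 1] + 0.5 * meta$age
  res <- residualize(scores, meta)
  X <- cbind(meta$age, as.numeric(factor(meta$sex)), as.numeric(factor(meta$center)))
  for (l in 1:2) {
    cors <- abs(cor(res[, , l], X))
    expect_true(all(cors < 1e-10))
  }
  # scores equal to an exact covariate function vanish
  scores2 <- array(2 * meta$age, c(n, 5, 1))
  expect_lt(max(abs(residualize(scores2, meta))), 1e-9)
})

test_that("rank-deficient covariate designs are rejected by name", {
  meta <- simple_meta(20)
  meta$dup <- meta$age
  expect_error(residualize(array(rnorm(20 * 5), c(20, 5, 1)), meta,
                           covariates = c("age", "dup")),
               "collinear.*dup")
  meta2 <- simple_meta(20)
  meta2$center <- "A"                      # constant factor: dropped, no error
  res <- residualize(array(rnorm(20 * 5), c(20, 5, 1)), meta2)
  expect_identical(dim(res), c(20L, 5L, 1L))
  expect_error(residualize(array(1, c(20, 5, 1)), meta[1:10, ]),
               "do not match")
})
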