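# shared fixtures, built in code

test_scheme <- function() gen_scheme(seed = 3)

# canonical single-fiber voxel with elevated free water (the package's
# recovery benchmark)
benchmark_voxel <- function() {
  mcm_fit(0.3, list(zeppelin(0.7, c(1, 1, 0) / sqrt(2), 1.7e-3, 0.3e-3)))
}

# independent oracle: FA / MD from the generic 3-eigenvalue tensor formulas
generic_tensor_metrics <- function(ev) {
  md <- mean(ev)
  fa <- sqrt(3 / 2) * sqrt(sum((ev - md)^2)) / sqrt(sum(ev^2))
  list(FA = fa, MD = md, AD = max(ev), RD = min(ev))
}

# data matrix whose empirical correlation matrix equals `target` exactly:
# orthonormalized centered noise recolored by the Cholesky factor
make_exact_cor_data <- function(n, target, seed = 1) {
  set.seed(seed)
  p <- ncol(target)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X))
  Q <- qr.Q(qr(X))
  Q <- sweep(Q, 2, colMeans(Q))         # re-center (qr can shift means)
  Q <- qr.Q(qr(Q))
  Z <- Q %*% chol(target)
  sweep(Z, 2, apply(Z, 2, sd), `/`)
}

# long profile tibble from a subjects x nodes x metrics array
array_to_profiles <- function(arr, metrics, bundle = "TEST") {
  ns <- dim(arr)[1]; nn <- dim(arr)[2]
  subjects <- sprintf("s%03d", seq_len(ns))
  out <- tidyr::expand_grid(metric = metrics, node = seq_len(nn),
                            subject = subjects)
  out$value <- arr[cbind(match(out$subject, subjects), out$node,
                         match(out$metric, metrics))]
  out$bundle <- bundle
  out[, c("subject", "bundle", "metric", "node", "value")]
}

simple_meta <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(subject = sprintf("s%03d", seq_len(n)),
                 group = rep(c("HC", "LLD"), length.out = n),
                 age = rnorm(n, 75, 6),
                 sex = sample(c("M", "F"), n, replace = TRUE),
                 center = sample(c("A", "B"), n, replace = TRUE))
}
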