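#' Two-sample Hotelling T-squared test
#'
#' Multivariate generalization of the two-sample Student t test:
#' `T2 = n1 n2 / (n1 + n2) * (xbar - ybar)' S^-1 (xbar - ybar)` with pooled
#' covariance `S`, converted to an F statistic
#' `F = T2 (n1 + n2 - L - 1) / (L (n1 + n2 - 2))` on `(L, n1 + n2 - L - 1)`
#' degrees of freedom. For `L = 1` the statistic equals the square of the
#' pooled t statistic.
#'
#' @param x,y Observation matrices (rows = subjects, columns = the L
#'   variables); vectors are treated as single-column matrices.
#' @return One-row tibble: `statistic` (T2), `f`, `df1`, `df2`, `p.value`.
#' @export
hotelling_t2 <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y)) stop("x and y must have the same number of columns", call. = FALSE)
  L <- ncol(x); n1 <- nrow(x); n2 <- nrow(y); n <- n1 + n2
  if (n <= L + 1) stop("need n1 + n2 > L + 1", call. = FALSE)
  d <- colMeans(x) - colMeans(y)
  S <- ((n1 - 1) * stats::cov(x) + (n2 - 1) * stats::cov(y)) / (n - 2)
  Sinv <- tryCatch(solve(S), error = function(e) {
    stop("singular pooled covariance; reduce the number of components (PCA)",
         call. = FALSE)
  })
  t2 <- as.numeric(n1 * n2 / n * t(d) %*% Sinv %*% d)
  f <- t2 * (n - L - 1) / (L * (n - 2))
  tibble::tibble(statistic = t2, f = f, df1 = L, df2 = n - L - 1,
                 p.value = stats::pf(f, L, n - L - 1, lower.tail = FALSE))
}

# --- vectorized node-wise engines -----------------------------------------
#
# scores enter as a list of L matrices (subjects x nodes) so each
# permutation costs a handful of dense matrix products rather than a loop
# of 100 small tests.

split_score_layers <- function(scores) {
  lapply(seq_len(dim(scores)[3]), function(l) scores[, , l, drop = TRUE])
}

# pooled within-group cross-product entries and mean differences per node
node_group_moments <- function(layers, g) {
  n1 <- sum(g); n2 <- length(g) - n1
  L <- length(layers)
  m1 <- lapply(layers, function(M) colSums(M[g, , drop = FALSE]) / n1)
  m2 <- lapply(layers, function(M) colSums(M[!g, , drop = FALSE]) / n2)
  centered <- lapply(seq_len(L), function(l) {
    M <- layers[[l]]
    M[g, ] <- sweep(M[g, , drop = FALSE], 2, m1[[l]])
    M[!g, ] <- sweep(M[!g, , drop = FALSE], 2, m2[[l]])
    M
  })
  S <- vector("list", L)
  for (l in seq_len(L)) {
    S[[l]] <- vector("list", L)
    for (m in l:L) S[[l]][[m]] <- colSums(centered[[l]] * centered[[m]]) / (n1 + n2 - 2)
  }
  d <- lapply(seq_len(L), function(l) m1[[l]] - m2[[l]])
  list(S = S, d = d, n1 = n1, n2 = n2)
}

# quadratic form d' S^-1 d per node, closed form for L <= 2
node_quadform <- function(S, d) {
  L <- length(d)
  if (L == 1) return(d[[1]]^2 / S[[1]][[1]])
  if (L == 2) {
    det <- S[[1]][[1]] * S[[2]][[2]] - S[[1]][[2]]^2
    return((d[[1]]^2 * S[[2]][[2]] - 2 * d[[1]] * d[[2]] * S[[1]][[2]] +
              d[[2]]^2 * S[[1]][[1]]) / det)
  }
  nodes <- length(d[[1]])
  out <- numeric(nodes)
  for (k in seq_len(nodes)) {
    Sk <- matrix(0, L, L)
    for (l in seq_len(L)) for (m in l:L) {
      Sk[l, m] <- Sk[m, l] <- S[[l]][[m]][k]
    }
    dk <- vapply(d, `[`, numeric(1), k)
    out[k] <- tryCatch(as.numeric(t(dk) %*% solve(Sk, dk)),
                       error = function(e) NA_real_)
  }
  out
}

# per-node Hotelling T2 / F / p for one labeling
node_hotelling <- function(layers, g) {
  L <- length(layers)
  mo <- node_group_moments(layers, g)
  n <- mo$n1 + mo$n2
  t2 <- mo$n1 * mo$n2 / n * node_quadform(mo$S, mo$d)
  f <- t2 * (n - L - 1) / (L * (n - 2))
  p <- stats::pf(f, L, n - L - 1, lower.tail = FALSE)
  list(t2 = t2, f = f, p = p, df1 = L, df2 = n - L - 1)
}

# per-node joint F test of the L score columns as predictors of y
# (both already covariate-residualized); df_adjust removes the residualized
# covariate degrees of freedom from the error df
node_association <- function(layers, y, df_adjust = 0) {
  L <- length(layers)
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  cl <- lapply(layers, function(M) sweep(M, 2, colMeans(M)))
  Sxy <- lapply(cl, function(M) colSums(M * yc))
  Sxx <- vector("list", L)
  for (l in seq_len(L)) {
    Sxx[[l]] <- vector("list", L)
    for (m in l:L) Sxx[[l]][[m]] <- colSums(cl[[l]] * cl[[m]])
  }
  ess <- node_quadform(Sxx, Sxy) * 1  # d' Sxx^-1 d with d = Sxy: explained SS
  r2 <- pmin(pmax(ess / syy, 0), 1)
  df2 <- n - L - 1 - df_adjust
  f <- (r2 / L) / ((1 - r2) / df2)
  p <- stats::pf(f, L, df2, lower.tail = FALSE)
  list(f = f, p = p, r2 = r2, df1 = L, df2 = df2, Sxy = Sxy, Sxx = Sxx)
}

# Cohen's d per component per node: (mean1 - mean2) / pooled SD
node_cohens_d <- function(layers, g) {
  mo <- node_group_moments(layers, g)
  lapply(seq_along(layers), function(l) {
    mo$d[[l]] / sqrt(mo$S[[l]][[l]])
  })
}

#' Pearson chi-squared test of a 2x2 contingency table
#'
#' Pearson's chi-squared without continuity correction, as used for
#' demographics tables (e.g. a gender-by-group count table). For a 2x2
#' table the statistic equals
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on one degree of freedom.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return One-row tibble: `statistic`, `df`, `p.value`.
#' @examples
#' contingency_chi2(matrix(c(9, 5, 26, 16), 2)) # ~0.03
#' @export
contingency_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("expected a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in the contingency table", call. = FALSE)
  }
  ct <- stats::chisq.test(table, correct = FALSE)
  tibble::tibble(statistic = as.numeric(ct$statistic),
                 df = as.numeric(ct$parameter),
                 p.value = ct$p.value)
}
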