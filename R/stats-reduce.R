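metric_order <- c("FW", "FA", "MD", "AD", "RD")

# long profile tibble (subject, bundle, metric, node, value) -> 3-D array
# [subject, node, metric] for one bundle
profiles_to_array <- function(profiles, bundle = NULL, metrics = NULL) {
  stopifnot(all(c("subject", "metric", "node", "value") %in% names(profiles)))
  if (!is.null(bundle)) profiles <- profiles[profiles$bundle == bundle, ]
  if (nrow(profiles) == 0) stop("no rows for the requested bundle", call. = FALSE)
  if (is.null(metrics)) {
    metrics <- unique(profiles$metric)
    metrics <- c(intersect(metric_order, metrics), setdiff(metrics, metric_order))
  }
  subjects <- unique(profiles$subject)
  nodes <- sort(unique(profiles$node))
  arr <- array(NA_real_, c(length(subjects), length(nodes), length(metrics)),
               dimnames = list(subjects, nodes, metrics))
  i <- cbind(match(profiles$subject, subjects),
             match(profiles$node, nodes),
             match(profiles$metric, metrics))
  keep <- !is.na(i[, 3])
  arr[i[keep, , drop = FALSE]] <- profiles$value[keep]
  arr
}

#' Prune strongly correlated metrics
#'
#' Computes pairwise Pearson correlations between the metrics over pooled
#' subject-by-node observations of one bundle and greedily removes metrics
#' until no absolute pairwise correlation exceeds the threshold. At each
#' step, among the metrics involved in a violating pair, the one with the
#' largest mean absolute correlation against all other retained metrics is
#' dropped (ties broken by preferring to keep the earlier metric in the
#' order FW, FA, MD, AD, RD).
#'
#' @param profiles Long profile tibble (`subject, bundle, metric, node,
#'   value`), one bundle (or pass `bundle`).
#' @param threshold Absolute correlation above which a pair is violating
#'   (default 0.8, strict inequality).
#' @param bundle Optional bundle name to subset.
#' @return A list of class `metric_pruning`: `retained`, `removed`,
#'   `cor_matrix` (full initial matrix, for reporting).
#' @export
prune_correlated <- function(profiles, threshold = 0.8, bundle = NULL) {
  arr <- profiles_to_array(profiles, bundle)
  metrics <- dimnames(arr)[[3]]
  if (length(metrics) < 2) stop("need at least 2 metrics to prune", call. = FALSE)
  mat <- matrix(arr, prod(dim(arr)[1:2]), dim(arr)[3],
                dimnames = list(NULL, metrics))
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  cm <- stats::cor(mat)
  retained <- metrics
  removed <- character()
  repeat {
    sub <- abs(cm[retained, retained, drop = FALSE])
    diag(sub) <- 0
    if (all(sub <= threshold) || length(retained) == 1) break
    in_pair <- apply(sub > threshold, 1, any)
    mean_r <- rowMeans(sub)
    cand <- retained[in_pair]
    worst <- cand[order(-mean_r[cand], -match(cand, metric_order))][1]
    removed <- c(removed, worst)
    retained <- setdiff(retained, worst)
  }
  structure(list(retained = retained, removed = removed, cor_matrix = cm),
            class = "metric_pruning")
}

#' @export
print.metric_pruning <- function(x, ...) {
  cat(sprintf("<metric_pruning: retained %s%s>\n",
              paste(x$retained, collapse = ", "),
              if (length(x$removed)) paste0("; removed ", paste(x$removed, collapse = ", "))
              else ""))
  invisible(x)
}

#' @export
tidy.metric_pruning <- function(x, ...) {
  cm <- x$cor_matrix
  tibble::tibble(
    metric1 = rep(rownames(cm), times = ncol(cm)),
    metric2 = rep(colnames(cm), each = nrow(cm)),
    correlation = as.numeric(cm),
    retained1 = rep(rownames(cm), times = ncol(cm)) %in% x$retained,
    retained2 = rep(colnames(cm), each = nrow(cm)) %in% x$retained
  )
}

#' PCA reduction of a bundle profile
#'
#' Pools the subject-by-node observations of one bundle (both groups
#' together), z-scores each metric over the pool, runs a PCA and keeps the
#' smallest number of components `L` whose cumulative explained variance
#' reaches `var_target`. Components are sign-ambiguous, so a fixed
#' orientation is applied: a component with an appreciable free-water
#' loading (|loading| >= 0.1) is oriented FW-positive — component increases
#' mean more free water, the direction in which such components are
#' reported — and any other component has its largest-magnitude loading
#' made positive. Zero-variance metrics are dropped with a warning.
#'
#' @param profiles Long profile tibble for one bundle.
#' @param var_target Cumulative explained-variance target (default 0.80).
#' @param metrics Metrics to use (e.g. the `retained` set from
#'   [prune_correlated()]); default all present.
#' @param bundle Optional bundle name to subset.
#' @return An object of class `pc_model`: `loadings` (metrics x L),
#'   `explained_variance_ratio` (all components), `L`, `metrics`, `center`,
#'   `scale`, `scores` (subjects x nodes x L array), `subjects`, `nodes`,
#'   `bundle`.
#' @export
fit_pca <- function(profiles, var_target = 0.80, metrics = NULL, bundle = NULL) {
  arr <- profiles_to_array(profiles, bundle, metrics)
  metrics <- dimnames(arr)[[3]]
  ns <- dim(arr)[1]; nn <- dim(arr)[2]
  mat <- matrix(arr, ns * nn, length(metrics), dimnames = list(NULL, metrics))
  cc <- stats::complete.cases(mat)
  if (!any(cc)) stop("no complete observations", call. = FALSE)
  sds <- apply(mat[cc, , drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance metric(s): ",
            paste(metrics[sds == 0], collapse = ", "), call. = FALSE)
    metrics <- metrics[sds > 0]
    mat <- mat[, metrics, drop = FALSE]
  }
  pc <- stats::prcomp(mat[cc, , drop = FALSE], center = TRUE, scale. = TRUE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  L <- which(cumsum(evr) >= var_target - 1e-12)[1]
  rot <- pc$rotation[, seq_len(L), drop = FALSE]
  flip <- vapply(seq_len(L), function(j) {
    v <- rot[, j]
    if ("FW" %in% names(v) && abs(v[["FW"]]) >= 0.1) {
      v[["FW"]] < 0
    } else {
      v[which.max(abs(v))] < 0
    }
  }, logical(1))
  rot[, flip] <- -rot[, flip]

  z <- sweep(sweep(mat, 2, pc$center), 2, pc$scale, `/`)
  sc <- z %*% rot                       # NA rows stay NA
  scores <- array(sc, c(ns, nn, L),
                  dimnames = list(dimnames(arr)[[1]], dimnames(arr)[[2]],
                                  paste0("PC", seq_len(L))))
  structure(list(loadings = rot, explained_variance_ratio = evr, L = L,
                 metrics = metrics, center = pc$center, scale = pc$scale,
                 scores = scores, subjects = dimnames(arr)[[1]],
                 nodes = as.integer(dimnames(arr)[[2]]),
                 bundle = if (!is.null(bundle)) bundle else unique(profiles$bundle)[1]),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model %s: L = %d (%.1f%% variance) from %s>\n",
              x$bundle, x$L, 100 * sum(x$explained_variance_ratio[seq_len(x$L)]),
              paste(x$metrics, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.pc_model <- function(x, ...) {
  tibble::tibble(
    metric = rep(rownames(x$loadings), times = x$L),
    component = rep(colnames(x$loadings), each = nrow(x$loadings)),
    loading = as.numeric(x$loadings)
  )
}

#' @export
glance.pc_model <- function(x, ...) {
  tibble::tibble(
    bundle = x$bundle, L = x$L,
    cumulative_variance = sum(x$explained_variance_ratio[seq_len(x$L)]),
    n_metrics = length(x$metrics),
    n_subjects = length(x$subjects), n_nodes = length(x$nodes)
  )
}

# covariate design matrix: intercept + age + sex + center indicators
covariate_design <- function(meta, covariates = c("age", "sex", "center")) {
  missing <- setdiff(covariates, names(meta))
  if (length(missing)) {
    stop("metadata lacks covariate column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cols <- lapply(covariates, function(cv) {
    v <- meta[[cv]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, cv))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) {
        m <- NULL                       # constant factor carries no information
      } else {
        m <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(m) <- paste0(cv, levels(f)[-1])
      }
    }
    m
  })
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  X
}

#' Remove covariate influence from PC scores
#'
#' Per node and per component, replaces the scores by the residuals of an
#' ordinary least-squares regression on the covariates (intercept + age +
#' sex + center indicators by default). Residuals are orthogonal to every
#' covariate column. Nodes with any missing score are set to `NA` for all
#' subjects (they are excluded downstream).
#'
#' @param scores Either a `pc_model` or its subjects x nodes x L score
#'   array.
#' @param meta Metadata tibble with one row per subject, rows matching the
#'   score array's subject order (matched on a `subject` column when
#'   present).
#' @param covariates Covariate column names (default `age, sex, center`).
#' @return Residual score array, same shape and dimnames.
#' @export
residualize <- function(scores, meta, covariates = c("age", "sex", "center")) {
  arr <- if (inherits(scores, "pc_model")) scores$scores else scores
  stopifnot(length(dim(arr)) == 3)
  if ("subject" %in% names(meta) && !is.null(dimnames(arr)[[1]])) {
    idx <- match(dimnames(arr)[[1]], meta$subject)
    if (any(is.na(idx))) stop("metadata is missing some subjects", call. = FALSE)
    meta <- meta[idx, ]
  }
  if (nrow(meta) != dim(arr)[1]) {
    stop("metadata rows do not match the score array", call. = FALSE)
  }
  X <- covariate_design(meta, covariates)
  qrX <- qr(X)
  out <- arr
  for (l in seq_len(dim(arr)[3])) {
    M <- arr[, , l]
    bad_nodes <- colSums(is.na(M)) > 0
    M[, bad_nodes] <- 0
    R <- qr.resid(qrX, M)
    R[, bad_nodes] <- NA_real_
    out[, , l] <- R
  }
  attr(out, "covariates") <- colnames(X)[-1]
  out
}
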