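#' Permutation cluster-size familywise error correction
#'
#' Given a function mapping a labeling to per-node p-values, records for
#' every permutation the maximum run length of contiguous nodes with
#' `p < alpha` (missing nodes break a run). The FWE-corrected cluster size
#' is the ceiling of the empirical (1 - alpha) quantile (type "higher") of
#' that null distribution; observed clusters at least that long are marked
#' significant. The observed labeling is included as the first permutation,
#' so the reported familywise p-value (`p_fwe`, the proportion of null
#' maxima at least as large as the observed maximum) is never zero.
#'
#' @param p_fun Function taking one labeling (a vector like `labels`) and
#'   returning per-node p-values.
#' @param labels Observed labeling vector (group labels, or scores for an
#'   association test); permutations shuffle it.
#' @param n_perm Number of permutations (default 10000; fewer than 100
#'   triggers a warning).
#' @param alpha Cluster-forming and reporting level (default 0.05).
#' @param seed Integer seed for the shuffles.
#' @param perms Optional matrix of labelings (one column per permutation,
#'   e.g. a full enumeration on a tiny design); overrides `n_perm`/`seed`.
#' @return List of class `fwe_result`: `p` (observed per-node p),
#'   `clusters` (tibble `start, end, length, significant`), `significant`
#'   (logical per node), `fwe_cluster_size`, `null_max`, `p_fwe`,
#'   `n_perm`, `alpha`.
#' @export
permutation_fwe <- function(p_fun, labels, n_perm = 10000, alpha = 0.05,
                            seed = 1, perms = NULL) {
  p_obs <- p_fun(labels)
  obs_runs <- logical_runs(p_obs < alpha)
  obs_max <- if (nrow(obs_runs)) max(obs_runs$length) else 0L

  if (is.null(perms)) {
    if (n_perm < 100) warning("n_perm < 100 gives a coarse null distribution", call. = FALSE)
    rng <- make_rng(seed, 7L)
    null_max <- integer(n_perm)
    null_max[1] <- obs_max
    for (k in seq_len(n_perm - 1)) {
      lab_k <- labels[rng$sample_int(length(labels))]
      runs <- logical_runs(p_fun(lab_k) < alpha)
      null_max[k + 1] <- if (nrow(runs)) max(runs$length) else 0L
    }
  } else {
    perms <- as.matrix(perms)
    null_max <- integer(ncol(perms))
    for (k in seq_len(ncol(perms))) {
      runs <- logical_runs(p_fun(perms[, k]) < alpha)
      null_max[k] <- if (nrow(runs)) max(runs$length) else 0L
    }
    n_perm <- ncol(perms)
  }

  # smallest cluster size whose null exceedance probability is <= alpha:
  # the exactly valid discrete version of the (1 - alpha) "higher" quantile
  thr <- 0L
  while (mean(null_max >= thr) > alpha) thr <- thr + 1L
  sig <- rep(FALSE, length(p_obs))
  if (nrow(obs_runs)) {
    obs_runs$significant <- obs_runs$length >= thr
    for (i in which(obs_runs$significant)) {
      sig[obs_runs$start[i]:obs_runs$end[i]] <- TRUE
    }
  } else {
    obs_runs$significant <- logical(0)
  }
  structure(list(p = p_obs, clusters = obs_runs, significant = sig,
                 fwe_cluster_size = thr, null_max = null_max,
                 p_fwe = mean(null_max >= obs_max),
                 n_perm = n_perm, alpha = alpha),
            class = "fwe_result")
}

#' Pointwise group comparison along a tract
#'
#' Per-node two-sample Hotelling T2 between the two groups' residualized PC
#' scores, with per-component Cohen's d effect sizes.
#'
#' @param scores Residualized subjects x nodes x L array (see
#'   [residualize()]).
#' @param labels Logical vector, `TRUE` for the reference group; d is
#'   computed as (reference mean - other mean) / pooled SD.
#' @return Tibble: `node, statistic (T2), f, df1, df2, p.value`, one
#'   `d_PC*` column per component.
#' @export
group_test_along_tract <- function(scores, labels) {
  stopifnot(length(dim(scores)) == 3, is.logical(labels),
            length(labels) == dim(scores)[1])
  if (sum(labels) < 3 || sum(!labels) < 3) {
    stop("each group needs at least 3 subjects", call. = FALSE)
  }
  layers <- split_score_layers(scores)
  ht <- node_hotelling(layers, labels)
  d <- node_cohens_d(layers, labels)
  out <- tibble::tibble(node = seq_along(ht$t2), statistic = ht$t2, f = ht$f,
                        df1 = ht$df1, df2 = ht$df2, p.value = ht$p)
  for (l in seq_along(d)) out[[paste0("d_PC", l)]] <- d[[l]]
  out
}

#' Pointwise score association along a tract
#'
#' Per-node joint F test of the L residualized PC scores as predictors of a
#' (covariate-residualized) clinical score, with an effect size `r`: the
#' signed partial correlation when `L = 1`, and `sqrt(partial R^2)` carrying
#' the sign of the largest-magnitude PC coefficient when `L > 1` (per-PC
#' partial correlations are also returned).
#'
#' @param scores Residualized subjects x nodes x L array, restricted to the
#'   group of interest.
#' @param score Residualized clinical score vector (same subjects).
#' @param df_adjust Degrees of freedom consumed by the residualization
#'   (number of covariate columns), subtracted from the error df.
#' @return Tibble: `node, f, df1, df2, p.value, r`, plus per-component
#'   `r_PC*` columns.
#' @export
association_along_tract <- function(scores, score, df_adjust = 0) {
  stopifnot(length(dim(scores)) == 3, length(score) == dim(scores)[1])
  layers <- split_score_layers(scores)
  as_ <- node_association(layers, score, df_adjust)
  L <- length(layers)
  n <- length(score)
  # per-PC marginal correlations with the score
  r_pc <- lapply(layers, function(M) {
    suppressWarnings(as.numeric(stats::cor(M, score)))
  })
  if (L == 1) {
    r <- r_pc[[1]]
  } else {
    dom <- mapply(function(...) {
      v <- c(...)
      if (all(is.na(v))) NA_real_ else v[which.max(abs(v))]
    }, r_pc[[1]], r_pc[[2]])
    if (L > 2) {
      # dominant coefficient across all components
      allr <- do.call(cbind, r_pc)
      dom <- apply(allr, 1, function(v) {
        if (all(is.na(v))) NA_real_ else v[which.max(abs(v))]
      })
    }
    r <- sign(dom) * sqrt(as_$r2)
  }
  out <- tibble::tibble(node = seq_along(as_$f), f = as_$f, df1 = as_$df1,
                        df2 = as_$df2, p.value = as_$p, r = r)
  for (l in seq_len(L)) out[[paste0("r_PC", l)]] <- r_pc[[l]]
  out
}

# shared reduction: prune -> PCA -> residualize
reduce_profiles <- function(profiles, meta, bundle = NULL,
                            prune_threshold = 0.8, var_target = 0.8,
                            covariates = c("age", "sex", "center")) {
  if (is.null(bundle)) {
    bundles <- unique(profiles$bundle)
    if (length(bundles) > 1) {
      stop("several bundles present; pass `bundle`", call. = FALSE)
    }
    bundle <- bundles
  }
  pruning <- prune_correlated(profiles, prune_threshold, bundle)
  pc <- fit_pca(profiles, var_target, metrics = pruning$retained, bundle = bundle)
  idx <- match(pc$subjects, meta$subject)
  if (any(is.na(idx))) stop("metadata is missing some subjects", call. = FALSE)
  meta <- meta[idx, ]
  res <- residualize(pc, meta, covariates)
  list(pruning = pruning, pc = pc, scores = res, meta = meta, bundle = bundle,
       covariates = covariates)
}

#' Along-tract group analysis of one bundle
#'
#' Full statistics chain for a bundle profile dataset: prune correlated
#' metrics, reduce to principal components (cumulative variance target),
#' residualize covariates, test the groups node by node with Hotelling T2,
#' and control the familywise error over the 100 nodes with a
#' permutation-null cluster-size threshold (group labels are shuffled on
#' the residualized scores).
#'
#' @param profiles Long profile tibble (`subject, bundle, metric, node,
#'   value`).
#' @param meta Subject metadata tibble (`subject, group, age, sex, center`,
#'   optionally clinical scores).
#' @param bundle Bundle to analyse (required when several are present).
#' @param prune_threshold Absolute-correlation pruning threshold.
#' @param var_target PCA cumulative explained-variance target.
#' @param covariates Covariate columns residualized out.
#' @param alpha Cluster-forming and reporting level.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param ref_group Group treated as reference for the sign of Cohen's d
#'   (default the alphabetically first group label).
#' @return An `alongtract_result`; see [tidy.alongtract_result()].
#' @export
alongtract_group_test <- function(profiles, meta, bundle = NULL,
                                  prune_threshold = 0.8, var_target = 0.8,
                                  covariates = c("age", "sex", "center"),
                                  alpha = 0.05, n_perm = 10000, seed = 1,
                                  ref_group = NULL) {
  red <- reduce_profiles(profiles, meta, bundle, prune_threshold, var_target,
                         covariates)
  grp <- red$meta$group
  lev <- sort(unique(grp))
  if (length(lev) != 2) stop("need exactly 2 groups", call. = FALSE)
  if (is.null(ref_group)) ref_group <- lev[1]
  g <- grp == ref_group
  layers <- split_score_layers(red$scores)
  p_fun <- function(lab) node_hotelling(layers, lab)$p
  fwe <- permutation_fwe(p_fun, g, n_perm = n_perm, alpha = alpha, seed = seed)
  tab <- group_test_along_tract(red$scores, g)
  tab$significant <- fwe$significant
  new_alongtract_result(tab, fwe, red, mode = "group", seed = seed,
                        extra = list(ref_group = ref_group,
                                     groups = lev))
}

#' Along-tract clinical-score association within a group
#'
#' Same reduction chain as [alongtract_group_test()], restricted afterwards
#' to one group (the PCA itself is fitted on all subjects pooled). Per node,
#' the association between a clinical score and the PC scores is tested
#' with a joint F test; covariates are residualized out of both sides once,
#' and permutations shuffle the residualized score.
#'
#' @inheritParams alongtract_group_test
#' @param score_col Metadata column holding the clinical score (default
#'   `"AES"`); must be complete for the analysed group.
#' @param group Group analysed (default `"LLD"`).
#' @return An `alongtract_result`.
#' @export
alongtract_association <- function(profiles, meta, bundle = NULL,
                                   score_col = "AES", group = "LLD",
                                   prune_threshold = 0.8, var_target = 0.8,
                                   covariates = c("age", "sex", "center"),
                                   alpha = 0.05, n_perm = 10000, seed = 1) {
  red <- reduce_profiles(profiles, meta, bundle, prune_threshold, var_target,
                         covariates)
  in_grp <- red$meta$group == group
  if (sum(in_grp) < 5) stop("too few subjects in the analysed group", call. = FALSE)
  score <- red$meta[[score_col]][in_grp]
  if (is.null(score) || any(is.na(score))) {
    stop(sprintf("'%s' must be present for every %s subject", score_col, group),
         call. = FALSE)
  }
  X <- covariate_design(red$meta[in_grp, ], covariates)
  score_res <- as.numeric(qr.resid(qr(X), score))
  scores <- red$scores[in_grp, , , drop = FALSE]
  layers <- split_score_layers(scores)
  df_adj <- ncol(X) - 1
  p_fun <- function(sc) node_association(layers, sc, df_adj)$p
  fwe <- permutation_fwe(p_fun, score_res, n_perm = n_perm, alpha = alpha,
                         seed = seed)
  tab <- association_along_tract(scores, score_res, df_adj)
  tab$significant <- fwe$significant
  new_alongtract_result(tab, fwe, red, mode = "association", seed = seed,
                        extra = list(score_col = score_col, group = group))
}

new_alongtract_result <- function(tab, fwe, red, mode, seed, extra = list()) {
  structure(c(list(table = tab, bundle = red$bundle, mode = mode,
                   fwe_cluster_size = fwe$fwe_cluster_size,
                   clusters = fwe$clusters, null_max = fwe$null_max,
                   p_fwe = fwe$p_fwe, n_perm = fwe$n_perm, alpha = fwe$alpha,
                   pc_model = red$pc, pruning = red$pruning, seed = seed),
              extra),
            class = "alongtract_result")
}

#' @export
print.alongtract_result <- function(x, ...) {
  nsig <- sum(x$table$significant, na.rm = TRUE)
  cat(sprintf("<alongtract_result %s (%s): L = %d, FWE cluster size %d, %d significant node(s)>\n",
              x$bundle, x$mode, x$pc_model$L, x$fwe_cluster_size, nsig))
  invisible(x)
}

#' Tidy an along-tract result
#'
#' @param x An `alongtract_result`.
#' @param ... Unused.
#' @return The per-node results tibble (`node`, statistic columns, `p.value`,
#'   effect sizes, `significant`), with the bundle name prepended.
#' @export
tidy.alongtract_result <- function(x, ...) {
  tibble::add_column(x$table, bundle = x$bundle, .before = 1)
}

#' @export
glance.alongtract_result <- function(x, ...) {
  tibble::tibble(bundle = x$bundle, mode = x$mode, L = x$pc_model$L,
                 retained_metrics = paste(x$pruning$retained, collapse = ","),
                 fwe_cluster_size = x$fwe_cluster_size,
                 n_significant_nodes = sum(x$table$significant, na.rm = TRUE),
                 n_clusters = sum(x$clusters$significant),
                 p_fwe = x$p_fwe, n_perm = x$n_perm, alpha = x$alpha)
}
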