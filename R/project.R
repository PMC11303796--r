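#' Projection configuration
#'
#' Controls how voxel metric values are carried onto centroid nodes.
#'
#' @param kernel Distance-weighting kernel: `"inverse"` gives a point at
#'   distance `d` from its node the weight `1 / (1 + d / h)`, `"gaussian"`
#'   gives `exp(-d^2 / (2 h^2))`; `h` is the centroid's inter-node arc
#'   spacing, so weights are scale-normalized.
#' @param lookup `"nearest"` reads each streamline vertex's metric from its
#'   containing voxel; `"trilinear"` interpolates the eight neighbours.
#' @param min_streamlines Bundles with fewer streamlines are skipped by
#'   [build_subject_profiles()].
#' @return A list of class `projection_config`.
#' @export
projection_config <- function(kernel = c("inverse", "gaussian"),
                              lookup = c("nearest", "trilinear"),
                              min_streamlines = 5) {
  structure(list(kernel = match.arg(kernel), lookup = match.arg(lookup),
                 min_streamlines = min_streamlines),
            class = "projection_config")
}

# world (mm) -> continuous 1-based voxel index
world_to_voxel <- function(points, affine) {
  inv <- solve(affine)
  v <- cbind(points, 1) %*% t(inv)
  v[, 1:3, drop = FALSE] + 1
}

sample_volume <- function(vol, vox, mode = "nearest") {
  dd <- dim(vol)
  if (mode == "nearest") {
    ijk <- round(vox)
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= dd[1] &
      ijk[, 2] >= 1 & ijk[, 2] <= dd[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= dd[3]
    out <- rep(NA_real_, nrow(vox))
    if (any(ok)) {
      lin <- (ijk[ok, 3] - 1) * dd[1] * dd[2] + (ijk[ok, 2] - 1) * dd[1] + ijk[ok, 1]
      out[ok] <- vol[lin]
    }
    return(list(values = out, in_bounds = ok))
  }
  # trilinear
  f <- floor(vox)
  ok <- f[, 1] >= 1 & f[, 1] + 1 <= dd[1] &
    f[, 2] >= 1 & f[, 2] + 1 <= dd[2] &
    f[, 3] >= 1 & f[, 3] + 1 <= dd[3]
  out <- rep(NA_real_, nrow(vox))
  if (any(ok)) {
    fv <- f[ok, , drop = FALSE]
    t3 <- vox[ok, , drop = FALSE] - fv
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) t3[, 1] else 1 - t3[, 1]) *
        (if (dy) t3[, 2] else 1 - t3[, 2]) *
        (if (dz) t3[, 3] else 1 - t3[, 3])
      lin <- (fv[, 3] + dz - 1) * dd[1] * dd[2] + (fv[, 2] + dy - 1) * dd[1] +
        (fv[, 1] + dx)
      acc <- acc + w * vol[lin]
    }
    out[ok] <- acc
  }
  list(values = out, in_bounds = ok)
}

# nearest centroid node (index) and distance for each point; exact
# vectorized search in blocks (the node count is small, default 100)
nearest_node <- function(points, nodes, block = 8192L) {
  n <- nrow(points)
  idx <- integer(n); dist <- numeric(n)
  nn2 <- rowSums(nodes^2)
  for (start in seq(1, n, by = block)) {
    rows <- start:min(start + block - 1, n)
    p <- points[rows, , drop = FALSE]
    d2 <- outer(rowSums(p^2), nn2, `+`) - 2 * p %*% t(nodes)
    j <- max.col(-d2, ties.method = "first")
    idx[rows] <- j
    dist[rows] <- sqrt(pmax(d2[cbind(seq_along(rows), j)], 0))
  }
  list(index = idx, dist = dist)
}

#' Project metric volumes onto a centroid line
#'
#' Every streamline vertex reads its metric values from the volumes (voxel
#' lookup through the affine), is assigned to its nearest centroid node,
#' and contributes to that node's value with a weight that decreases with
#' its distance to the node — so spurious streamlines far from the centroid
#' have little influence. Out-of-bounds vertices are dropped (count
#' reported); nodes receiving no vertex are `NA`.
#'
#' @param metrics Named list of 3-D arrays on a common grid.
#' @param affine 4 x 4 voxel-to-world (RAS mm) matrix of that grid.
#' @param bundle A [bundle()] in world mm.
#' @param centroid A [compute_centroid()] result for the bundle.
#' @param config A [projection_config()].
#' @return A tibble of class `tract_profile`, long form: `bundle, metric,
#'   node, value, weight_sum, n_points`; `attr(, "n_dropped")` counts
#'   out-of-bounds vertices.
#' @export
project_metrics <- function(metrics, affine, bundle, centroid,
                            config = projection_config()) {
  stopifnot(inherits(bundle, "bundle"), inherits(centroid, "centroid_line"))
  if (!is.list(metrics) || is.null(names(metrics)) ||
      length(unique(lapply(metrics, dim))) != 1) {
    stop("`metrics` must be a named list of arrays on one grid", call. = FALSE)
  }
  points <- do.call(rbind, bundle$streamlines)
  vox <- world_to_voxel(points, affine)
  s <- nrow(centroid$nodes)
  h <- centroid$spacing

  first <- sample_volume(metrics[[1]], vox, config$lookup)
  ok <- first$in_bounds & !is.na(first$values)
  n_dropped <- sum(!first$in_bounds)
  if (!any(first$in_bounds)) stop("all bundle points fall outside the volume", call. = FALSE)

  nn <- nearest_node(points[ok, , drop = FALSE], centroid$nodes)
  w <- switch(config$kernel,
              inverse = 1 / (1 + nn$dist / h),
              gaussian = exp(-nn$dist^2 / (2 * h^2)))
  node_f <- factor(nn$index, levels = seq_len(s))
  wsum <- as.numeric(tapply(w, node_f, sum, default = 0))
  npts <- as.integer(tapply(rep(1L, length(w)), node_f, sum, default = 0L))

  vals <- lapply(names(metrics), function(m) {
    v <- if (m == names(metrics)[1]) first$values[ok] else {
      sample_volume(metrics[[m]], vox, config$lookup)$values[ok]
    }
    num <- as.numeric(tapply(w * v, node_f, sum, default = 0))
    out <- ifelse(wsum > 0, num / wsum, NA_real_)
    # a weighted mean lies within its contributors' range; clamping removes
    # last-ulp float drift (constant field in -> identical constant out)
    lo <- as.numeric(tapply(v, node_f, min, default = NA))
    hi <- as.numeric(tapply(v, node_f, max, default = NA))
    pmin(pmax(out, lo), hi)
  })
  names(vals) <- names(metrics)

  out <- tidyr::expand_grid(metric = names(metrics), node = seq_len(s))
  out$value <- unlist(vals, use.names = FALSE)
  out$weight_sum <- rep(wsum, times = length(metrics))
  out$n_points <- rep(npts, times = length(metrics))
  out <- tibble::add_column(out, bundle = bundle$name, .before = 1)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("tract_profile", class(out))
  out
}

#' Build all bundle profiles for one subject
#'
#' Runs [compute_centroid()] and [project_metrics()] over a list of bundles
#' and stacks the results. Bundles with fewer than
#' `config$min_streamlines` streamlines are skipped with a warning.
#'
#' @param metrics Named list of metric arrays (one grid).
#' @param affine The grid's 4 x 4 voxel-to-world matrix.
#' @param bundles List of [bundle()]s.
#' @param subject_id Identifier written into the output.
#' @param s Nodes per centroid (default 100).
#' @param config A [projection_config()].
#' @return Long tibble `subject, bundle, metric, node, value, weight_sum,
#'   n_points`.
#' @export
build_subject_profiles <- function(metrics, affine, bundles, subject_id,
                                   s = 100, config = projection_config()) {
  rows <- list()
  for (b in bundles) {
    if (length(b$streamlines) < config$min_streamlines) {
      warning(sprintf("bundle %s skipped: %d < %d streamlines",
                      b$name, length(b$streamlines), config$min_streamlines),
              call. = FALSE)
      next
    }
    cl <- compute_centroid(b, s)
    rows[[b$name]] <- project_metrics(metrics, affine, b, cl, config)
  }
  if (length(rows) == 0) stop("no bundle passed the streamline-count filter", call. = FALSE)
  out <- dplyr::bind_rows(rows)
  tibble::add_column(out, subject = subject_id, .before = 1)
}
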