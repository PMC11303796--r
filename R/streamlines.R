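#' Streamline and bundle containers
#'
#' A streamline is an n x 3 numeric matrix of world-space coordinates (mm,
#' RAS), with at least two points. A bundle is a named collection of
#' streamlines.
#'
#' @param points Numeric n x 3 matrix, n >= 2, finite, with nonzero total
#'   length.
#' @return `streamline()` returns the validated matrix with class
#'   `streamline`; `bundle()` a list of class `bundle`.
#' @export
streamline <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3 || nrow(points) < 2) {
    stop("a streamline needs an n x 3 matrix with n >= 2", call. = FALSE)
  }
  if (any(!is.finite(points))) stop("streamline coordinates must be finite", call. = FALSE)
  if (streamline_length(points) <= 0) {
    stop("degenerate streamline: all points identical", call. = FALSE)
  }
  class(points) <- c("streamline", class(points))
  points
}

#' @rdname streamline
#' @param name Bundle label (e.g. `"ATR_left"`).
#' @param streamlines List of point matrices.
#' @export
bundle <- function(name, streamlines) {
  if (length(streamlines) < 1) stop("a bundle needs at least one streamline", call. = FALSE)
  streamlines <- lapply(streamlines, function(s) unclass(streamline(s)))
  structure(list(name = name, streamlines = streamlines), class = "bundle")
}

#' @export
print.bundle <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("<bundle %s: %d streamlines, %d-%d points each>\n",
              x$name, length(x$streamlines), min(np), max(np)))
  invisible(x)
}

streamline_length <- function(points) {
  d <- diff(points)
  sum(sqrt(rowSums(d * d)))
}

#' Resample a streamline to equidistant points
#'
#' Arc-length parameterization of the polyline, sampled at `n` equally
#' spaced arc positions including both endpoints.
#'
#' @param points An n x 3 point matrix (or [streamline()]).
#' @param n Number of output points (>= 2).
#' @return An n x 3 matrix; endpoints preserved exactly.
#' @examples
#' resample_streamline(rbind(c(0, 0, 0), c(99, 0, 0)), 100)[, 1] # 0..99
#' @export
resample_streamline <- function(points, n) {
  points <- unclass(streamline(points))
  stopifnot(n >= 2)
  seg <- sqrt(rowSums(diff(points)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  target <- seq(0, total, length.out = n)
  # collapse zero-length segments so approx() sees strictly increasing x
  keep <- c(TRUE, seg > 0)
  arc_u <- arc[keep]; pts_u <- points[keep, , drop = FALSE]
  out <- vapply(1:3, function(k) {
    stats::approx(arc_u, pts_u[, k], xout = target, rule = 2)$y
  }, numeric(n))
  out[1, ] <- points[1, ]
  out[n, ] <- points[nrow(points), ]
  out
}

#' Minimum-direct-flip distance between two streamlines
#'
#' Both streamlines are resampled to `n` points; the direct distance is the
#' mean pointwise Euclidean distance, the flipped distance the same with
#' one streamline reversed, and the MDF is the smaller of the two. It is
#' symmetric, non-negative and zero for streamlines identical up to
#' orientation.
#'
#' @param a,b Point matrices.
#' @param n Resampling count used for the comparison.
#' @return Distance in mm.
#' @export
mdf_distance <- function(a, b, n = 20) {
  a <- resample_streamline(a, n)
  b <- resample_streamline(b, n)
  direct <- mean(sqrt(rowSums((a - b)^2)))
  flipped <- mean(sqrt(rowSums((a - b[n:1, ])^2)))
  min(direct, flipped)
}

# deterministic, order-independent flip reference: largest endpoint
# separation, ties by lexicographic first point
flip_reference <- function(resampled) {
  span <- vapply(resampled, function(p) {
    sum((p[nrow(p), ] - p[1, ])^2)
  }, numeric(1))
  best <- which(span == max(span))
  if (length(best) > 1) {
    firsts <- t(vapply(resampled[best], function(p) p[1, ], numeric(3)))
    ord <- do.call(order, as.data.frame(firsts))
    best <- best[ord[1]]
  }
  best[1]
}

#' Centroid line of a bundle
#'
#' All streamlines are resampled to `s` points, orientation-aligned
#' (flipped or not, whichever minimizes the direct distance) against a
#' deterministic reference streamline, averaged pointwise, and the mean
#' polyline is re-resampled to `s` equidistant nodes. The reference is the
#' streamline with the largest endpoint separation, so the result does not
#' depend on storage order.
#'
#' @param bundle A [bundle()].
#' @param s Number of centroid nodes (default 100).
#' @return A list of class `centroid_line` with `nodes` (s x 3 matrix),
#'   `spacing` (inter-node arc spacing, mm) and `name`.
#' @export
compute_centroid <- function(bundle, s = 100) {
  stopifnot(inherits(bundle, "bundle"))
  res <- lapply(bundle$streamlines, resample_streamline, n = s)
  ref <- res[[flip_reference(res)]]
  aligned <- lapply(res, function(p) {
    direct <- mean(sqrt(rowSums((p - ref)^2)))
    flipped <- mean(sqrt(rowSums((p[s:1, ] - ref)^2)))
    if (flipped < direct) p[s:1, ] else p
  })
  mean_line <- Reduce(`+`, aligned) / length(aligned)
  nodes <- resample_streamline(mean_line, s)
  structure(list(nodes = nodes,
                 spacing = streamline_length(nodes) / (s - 1),
                 name = bundle$name),
            class = "centroid_line")
}

#' @export
print.centroid_line <- function(x, ...) {
  cat(sprintf("<centroid_line %s: %d nodes, spacing %.3f mm>\n",
              x$name %||% "", nrow(x$nodes), x$spacing))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
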