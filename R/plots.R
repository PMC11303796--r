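#' Plot bundle profiles
#'
#' Mean and standard-deviation ribbon of each metric along the tract,
#' across subjects.
#'
#' @param profiles Long profile tibble (`subject, bundle, metric, node,
#'   value`).
#' @param bundle Optional bundle to subset.
#' @return A ggplot object, faceted by metric.
#' @export
plot_tract_profiles <- function(profiles, bundle = NULL) {
  if (!is.null(bundle)) profiles <- profiles[profiles$bundle == bundle, ]
  summ <- dplyr::summarise(
    dplyr::group_by(profiles, .data$bundle, .data$metric, .data$node),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$node, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "node along tract", y = "metric value",
                  title = unique(summ$bundle)[1]) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.alongtract_result <- function(object, ...) {
  tab <- object$table
  tab$neglog10p <- -log10(pmax(tab$p.value, 1e-16))
  gg <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$node, y = .data$neglog10p)) +
    ggplot2::geom_col(fill = "grey70", width = 1) +
    ggplot2::geom_point(data = tab[which(tab$significant), ],
                        colour = "red", size = 1.2) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::labs(x = "node along tract", y = expression(-log[10](p)),
                  title = sprintf("%s (%s test), FWE cluster size %d",
                                  object$bundle, object$mode,
                                  object$fwe_cluster_size)) +
    ggplot2::theme_minimal()
  gg
}

#' @export
autoplot.pc_model <- function(object, ...) {
  ld <- tidy(object)
  evr <- object$explained_variance_ratio
  ld$component <- factor(ld$component)
  levels(ld$component) <- sprintf(
    "%s (%.1f%%)", levels(ld$component),
    100 * evr[as.integer(sub("PC", "", levels(ld$component)))])
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$metric, y = .data$loading)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(title = sprintf("%s: loadings (L = %d)", object$bundle, object$L),
                  x = NULL, y = "loading") +
    ggplot2::theme_minimal()
}
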