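# ggplot2 views of the merged network and its annotations.

#' Log-log degree distribution with the power-law regression line
#'
#' @param object A `merged_network` tibble.
#' @param ... Unused.
#' @return A ggplot: degree frequency on log-log axes, with the
#'   least-squares regression line when a fit is available.
#' @export
autoplot.merged_network <- function(object, ...) {
  ds <- degree_stats(object)
  h <- table(ds$degrees$degree[ds$degrees$degree > 0])
  df <- tibble::tibble(degree = as.numeric(names(h)),
                       count = as.numeric(h))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$degree,
                                        y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "node degree k", y = "number of nodes",
                  title = "Degree distribution")
  if (!is.null(ds$fit)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(
        degree = df$degree,
        count = exp(ds$fit$intercept) * df$degree^ds$fit$slope
      ),
      linetype = "dashed", colour = "red"
    ) +
      ggplot2::labs(subtitle = sprintf("slope %.2f, adj R² %.2f",
                                       ds$fit$slope, ds$fit$adj_r2))
  }
  p
}

#' Phylogenetic vs functional distance scatter of network edges
#'
#' @param annotated Edge table from [annotate_edges()].
#' @return A ggplot: one point per edge, colored by association sign,
#'   shaped by within- vs cross-site.
#' @export
plot_edge_distances <- function(annotated) {
  df <- annotated[annotated$covered, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$phylo_dist, y = .data$func_dist,
    colour = factor(.data$sign, c(-1, 1), c("exclusion", "co-occurrence")),
    shape = .data$within_site
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(exclusion = "firebrick", `co-occurrence` = "forestgreen")
    ) +
    ggplot2::labs(x = "phylogenetic distance", y = "functional distance",
                  colour = "association", shape = "within site")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
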