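#' Coverage depth profile plot with the detected elevated segment
#'
#' @param assembly a `collapsed_assembly` (or any object with a `coverage`
#'   tibble of `pos`, `depth`).
#' @param call optional `ltr_call` whose boundaries are drawn as dashed lines.
#' @return a ggplot object.
#' @export
plot_coverage <- function(assembly, call = NULL) {
  cov <- if (is.list(assembly) && !is.null(assembly$coverage)) {
    assembly$coverage
  } else {
    tibble::as_tibble(assembly)
  }
  p <- ggplot2::ggplot(cov, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "position (bp)", y = "read depth",
                  title = "Assembly coverage profile") +
    ggplot2::theme_minimal()
  if (!is.null(call) && isTRUE(call$detected)) {
    p <- p + ggplot2::geom_vline(xintercept = c(call$start, call$end),
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @export
autoplot.similarity_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$target, y = .data$query,
                                 fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100),
                                  name = "% similarity") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Fragmented genome similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @param object an `fr_layout`; pass `clusters = ` a `group_assignment` to
#'   colour nodes by cluster.
#' @param clusters optional `group_assignment` tibble from
#'   [extract_clusters()].
#' @rdname layout_fr
#' @export
autoplot.fr_layout <- function(object, clusters = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(clusters)) {
    df <- dplyr::left_join(df, clusters, by = "node")
    aes <- ggplot2::aes(x = .data$x, y = .data$y, colour = .data$cluster)
  } else {
    aes <- ggplot2::aes(x = .data$x, y = .data$y)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$node), vjust = -1,
                       size = 3, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Force-directed genome network layout") +
    ggplot2::theme_minimal()
}

#' One-step growth curve plot
#'
#' @param series a `titer_series` (one-step kind).
#' @param fit optional `growth_fit`; latent/eclipse times are drawn as dashed
#'   lines.
#' @return a ggplot object.
#' @export
plot_growth_curve <- function(series, fit = NULL) {
  df <- tibble::as_tibble(series)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min,
                                        y = .data$pfu_per_ml,
                                        colour = .data$treatment)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (min)", y = "PFU/ml",
                  title = "One-step growth curve") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    marks <- c(fit$latent_min, fit$eclipse_min)
    p <- p + ggplot2::geom_vline(xintercept = marks[!is.na(marks)],
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
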