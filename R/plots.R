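#' Plot a relationship table
#'
#' One mark per relationship record: partners on the x axis, lag class on
#' the y axis, colour by nature, shape by causal role, facetted by seed and
#' task.
#'
#' @param object A `bg_relationships` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bg_relationships <- function(object, ...) {
  d <- tidy(object)
  d$lag_class <- factor(d$lag_class,
                        c("contemporaneous", "single_delayed",
                          "double_delayed"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$partner, y = .data$lag_class,
                                  colour = .data$nature,
                                  shape = .data$role)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_grid(seed ~ task) +
    ggplot2::labs(x = NULL, y = NULL, colour = "nature", shape = "role") +
    ggplot2::theme_minimal()
}

#' Plot a discovered time-series graph
#'
#' Nodes on a circle; one segment per significant link, coloured by lag,
#' solid for directed and dashed for undirected/conflicted marks.
#'
#' @param object A `bg_tsgraph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bg_tsgraph <- function(object, ...) {
  nodes <- attr(object, "nodes")
  theta <- seq(0, 2 * pi, length.out = length(nodes) + 1)[-1]
  pos <- tibble::tibble(node = nodes, x = cos(theta), y = sin(theta))
  links <- tidy(object)
  if (nrow(links)) {
    links <- links %>%
      dplyr::left_join(pos, by = c(i = "node")) %>%
      dplyr::left_join(pos, by = c(j = "node"), suffix = c("", "end"))
  }
  p <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$node)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (nrow(links)) {
    p <- p + ggplot2::geom_segment(
      data = links,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = factor(.data$lag),
                   linetype = .data$mark %in%
                     c("directed", "contemp_directed")),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "cm")),
      alpha = 0.7, inherit.aes = FALSE) +
      ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                                `FALSE` = "dashed"),
                                     guide = "none") +
      ggplot2::labs(colour = "lag")
  }
  p
}

#' Plot a concatenated panel
#'
#' Time courses of the ROI columns over a sample window, with block
#' boundaries marked.
#'
#' @param object A `bg_concat` series.
#' @param rois ROI subset (default: all).
#' @param window Sample range to show (default: first 400).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bg_concat <- function(object, rois = NULL, window = NULL, ...) {
  rois <- rois %||% roi_labels(object)
  window <- window %||% seq_len(min(400L, nrow(object)))
  d <- tibble::as_tibble(object)[window, c("t", rois)] %>%
    tidyr::pivot_longer(-"t", names_to = "roi", values_to = "signal")
  b <- attr(object, "boundaries")
  b <- b[b >= min(window) & b <= max(window)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$signal)) +
    ggplot2::geom_vline(xintercept = b, colour = "grey80") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$roi)) +
    ggplot2::labs(x = "sample", y = NULL) +
    ggplot2::theme_minimal()
}
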