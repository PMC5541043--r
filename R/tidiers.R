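#' Tidiers for hierseg result objects
#'
#' [tidy()] returns the per-component detail of a result as a tibble;
#' [glance()] returns a one-row summary.
#'
#' @param x A `hierseg_delta` or `hierseg_quadrants` object.
#' @param ... Unused.
#' @return A tibble.
#' @name hierseg-tidiers
NULL

#' @rdname hierseg-tidiers
#' @export
tidy.hierseg_delta <- function(x, ...) x$z

#' @rdname hierseg-tidiers
#' @export
glance.hierseg_delta <- function(x, ...) {
  tibble(delta = x$delta, w_rcond = rcond(x$w))
}

#' @rdname hierseg-tidiers
#' @export
tidy.hierseg_quadrants <- function(x, ...) {
  tibble(quadrant = names(x$fractions),
         n = as.integer(round(x$fractions * x$n)),
         fraction = unname(x$fractions))
}

#' @rdname hierseg-tidiers
#' @export
glance.hierseg_quadrants <- function(x, ...) {
  tibble(median_x = x$median_x, median_y = x$median_y, n = x$n)
}

#' Plot methods for hierseg objects
#'
#' `autoplot()` draws a hierarchy as stacked labeled interval bars, a meet
#' matrix or self-similarity matrix as a heat map, and a quadrant analysis
#' as the score scatter with median lines.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name hierseg-autoplot
NULL

#' @rdname hierseg-autoplot
#' @export
autoplot.hierseg_hierarchy <- function(object, ...) {
  h <- as_tibble(object)
  ggplot2::ggplot(h) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -.data$level, ymax = -.data$level + 0.9,
                   fill = .data$label),
      color = "grey20", linewidth = 0.2, show.legend = FALSE) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$start + .data$end) / 2,
                   y = -.data$level + 0.45, label = .data$label),
      size = 3) +
    ggplot2::scale_y_continuous(
      breaks = -seq_len(max(h$level)) + 0.45,
      labels = paste("level", seq_len(max(h$level)))) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname hierseg-autoplot
#' @export
autoplot.hierseg_meet <- function(object, ...) {
  matrix_heatmap(unclass(object), attr(object, "frame_rate"), "meet level")
}

#' @rdname hierseg-autoplot
#' @export
autoplot.hierseg_ssm <- function(object, ...) {
  matrix_heatmap(unclass(object), attr(object, "frame_rate"),
                 paste0(attr(object, "kind") %||% "", " similarity"))
}

matrix_heatmap <- function(m, frame_rate, legend) {
  fr <- frame_rate %||% 1
  df <- tidyr::expand_grid(u = seq_len(nrow(m)), v = seq_len(ncol(m)))
  df$value <- m[cbind(df$u, df$v)]
  ggplot2::ggplot(df, ggplot2::aes((.data$v - 1) / fr, (.data$u - 1) / fr,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "time (s)", y = "time (s)", fill = legend) +
    ggplot2::theme_minimal()
}

#' @rdname hierseg-autoplot
#' @export
autoplot.hierseg_quadrants <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$x, .data$y, color = .data$quadrant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$median_x, color = "red") +
    ggplot2::geom_hline(yintercept = object$median_y, color = "red") +
    ggplot2::theme_minimal()
}

#' @rdname hierseg-autoplot
#' @export
autoplot.hierseg_scores <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", color = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "score", y = "pairs") +
    ggplot2::theme_minimal()
}
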