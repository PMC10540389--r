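# ggplot2 front-ends for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a delta map
#'
#' @param object A `silksims_delta_map`.
#' @param ... Unused.
#' @return A ggplot raster of the per-mil enrichment (invalid pixels blank).
#' @export
autoplot.silksims_delta_map <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$delta)),
                           col = seq_len(ncol(object$delta)))
  df$delta <- as.vector(object$delta)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$delta)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", na.value = "grey20",
                                  name = expression(delta^13 * C ~ "(‰)")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a kinetics fit
#'
#' @param object A `silksims_fit`.
#' @param ... Unused.
#' @return A ggplot of the data points and the fitted curve.
#' @export
autoplot.silksims_fit <- function(object, ...) {
  tt <- seq(min(object$data$t), max(object$data$t), length.out = 200)
  curve <- tibble(t = tt, delta = predict(object, tt))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$t, .data$delta)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "time (h)", y = expression(delta^13 * C ~ "(‰)"),
                  title = object$model) +
    ggplot2::theme_minimal()
}

#' Plot a scene's compartment labels
#'
#' @param object A `silksims_scene`.
#' @param ... Unused.
#' @return A ggplot raster of the compartment classes.
#' @export
autoplot.silksims_scene <- function(object, ...) {
  lab <- object$label_image
  df <- tidyr::expand_grid(row = seq_len(nrow(lab)), col = seq_len(ncol(lab)))
  cls <- names(COMPARTMENT_CLASSES)[match(as.vector(lab), COMPARTMENT_CLASSES)]
  df$class <- factor(cls, levels = names(COMPARTMENT_CLASSES))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Violin summary of group measurements
#'
#' Violin plot with median and quartile lines, the standard display for the
#' per-cell and per-organelle group comparisons.
#'
#' @param data Measurement tibble.
#' @param value Measurement column (tidy-eval).
#' @param x Grouping column on the x axis (tidy-eval).
#' @param fill Optional fill grouping (tidy-eval), e.g. condition.
#' @return A ggplot.
#' @export
plot_group_violin <- function(data, value, x, fill = NULL) {
  val <- rlang::enquo(value); xx <- rlang::enquo(x); fl <- rlang::enquo(fill)
  aes <- if (rlang::quo_is_null(fl)) {
    ggplot2::aes(factor(!!xx), !!val)
  } else {
    ggplot2::aes(factor(!!xx), !!val, fill = factor(!!fl))
  }
  ggplot2::ggplot(data, aes) +
    ggplot2::geom_violin(draw_quantiles = c(0.25, 0.5, 0.75),
                         position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::labs(x = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
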