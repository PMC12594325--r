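# ggplot2 visualisations for the result types.

#' Plot a confusion matrix
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object (tile heatmap of counts).
#' @export
autoplot.metrics_report <- function(x, ...) {
  cm <- attr(x, "confusion")
  df <- as.data.frame(as.table(unclass(cm)))
  names(df) <- c("true", "pred", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true", fill = "count",
                  title = sprintf("Confusion matrix (accuracy %.3f)",
                                  x$accuracy))
}

#' Plot metric degradation across noise levels
#'
#' @param x A `robustness_table`.
#' @param metrics Which metric columns to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.robustness_table <- function(x, metrics = c("accuracy", "auc"), ...) {
  df <- tidy.robustness_table(x)
  df <- df[df$metric %in% metrics, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(sigma), y = "metric value",
                  title = "Noise robustness")
}

#' Plot training history
#'
#' @param x A `kct_fit`.
#' @param ... Unused.
#' @return A ggplot object with loss and accuracy curves per epoch.
#' @export
autoplot.kct_fit <- function(x, ...) {
  h <- x$history
  df <- rbind(
    tibble::tibble(epoch = h$epoch, value = h$loss, series = "train loss"),
    tibble::tibble(epoch = h$epoch, value = h$train_acc, series = "train accuracy"),
    tibble::tibble(epoch = h$epoch, value = h$val_acc, series = "val accuracy"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history")
}

#' Plot an image with an optional Grad-CAM overlay
#'
#' @param image H x W matrix in `[0, 1]`.
#' @param heatmap Optional H x W heatmap in `[0, 1]` (from [grad_cam()]).
#' @param alpha Overlay opacity.
#' @return A ggplot object.
#' @export
plot_image <- function(image, heatmap = NULL, alpha = 0.4) {
  df <- expand.grid(row = seq_len(nrow(image)), col = seq_len(ncol(image)))
  df$intensity <- as.vector(image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(heatmap)) {
    df$heat <- as.vector(heatmap)
    p <- p + ggplot2::geom_raster(data = df,
                                  ggplot2::aes(alpha = .data$heat),
                                  fill = "red") +
      ggplot2::scale_alpha(range = c(0, alpha))
  }
  p
}

#' Scatter plot of a 2-D embedding
#'
#' @param coords n x 2 matrix from [embed_2d()].
#' @param labels Point labels (colour).
#' @return A ggplot object.
#' @export
plot_embedding <- function(coords, labels) {
  df <- tibble::tibble(dim1 = coords[, 1], dim2 = coords[, 2],
                       label = as.factor(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(title = "Feature embedding")
}
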