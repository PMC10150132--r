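raster_df <- function(m) {
  tibble::tibble(
    x = rep(0:(ncol(m) - 1), each = nrow(m)),
    y = rep(0:(nrow(m) - 1), times = ncol(m)),
    value = as.vector(m))
}

#' Plot a phantom with its ground truth overlay
#'
#' Shows the mask with the midline and the four mid-axis keypoints.
#'
#' @param object A `phantom_truth`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phantom_truth <- function(object, ...) {
  df <- raster_df(object$mask)
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(.data$x, .data$y,
                                      fill = factor(.data$value))) +
    ggplot2::scale_fill_manual(values = c(`0` = "grey15", `1` = "grey85"),
                               guide = "none") +
    ggplot2::geom_path(data = object$midline,
                       ggplot2::aes(.data$x, .data$y),
                       colour = "steelblue", linewidth = 0.6) +
    ggplot2::geom_point(data = object$keypoints,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$point), size = 2.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s phantom, %.1f deg",
                                  object$spec$curvature_type, object$angle),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot keypoints over a mask
#'
#' @param mask 0/1 matrix.
#' @param kps A [keypoint_set()].
#' @param midline Optional `midline_path` to overlay.
#' @return A ggplot.
#' @export
plot_keypoints <- function(mask, kps, midline = NULL) {
  df <- raster_df(as_mask_matrix(mask))
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(.data$x, .data$y,
                                      fill = factor(.data$value))) +
    ggplot2::scale_fill_manual(values = c(`0` = "grey15", `1` = "grey85"),
                               guide = "none")
  if (!is.null(midline)) {
    p <- p + ggplot2::geom_path(data = midline,
                                ggplot2::aes(.data$x, .data$y),
                                colour = "steelblue", linewidth = 0.6)
  }
  p +
    ggplot2::geom_point(data = kps,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$point), size = 2.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-model angle predictions against ground truth
#'
#' @param object An `angle_report` from [mae_report()].
#' @param ... Unused.
#' @return A ggplot (predicted mean +/- sd versus truth, with the
#'   identity line).
#' @export
autoplot.angle_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$truth, .data$mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = "ground-truth angle (deg)",
                  y = "predicted angle (deg, mean +/- sd)",
                  title = sprintf("pooled MAE %.2f deg",
                                  attr(object, "mae_pooled"))) +
    ggplot2::theme_minimal()
}

#' Plot AP across the IoU threshold sweep
#'
#' @param object A `detection_result` from [mean_ap()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.detection_result <- function(object, ...) {
  ggplot2::ggplot(object$ap,
                  ggplot2::aes(.data$iou_threshold, .data$ap)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "IoU threshold", y = "average precision") +
    ggplot2::theme_minimal()
}
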