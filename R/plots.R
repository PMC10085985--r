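#' Plot a frame with optional spot overlay and heatmap
#'
#' @param image A frame (fluorescein matrix or RGB array).
#' @param spots Optional [detect_spots()] tibble to mark.
#' @param heatmap Optional [attribution_map()] matrix overlaid in red.
#' @return A ggplot.
#' @export
plot_frame <- function(image, spots = NULL, heatmap = NULL) {
  img <- as_fluor(image)
  df <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$value <- as.vector(t(img))  # row-major walk matches expand_grid order
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "#7CFC00",
                                 limits = c(0, 1), name = "fluorescein") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(heatmap)) {
    hd <- df
    hd$alpha <- as.vector(t(heatmap)) * 0.7
    p <- p + ggplot2::geom_raster(data = hd, fill = "red",
                                  ggplot2::aes(alpha = .data$alpha)) +
      ggplot2::scale_alpha_identity()
  }
  if (!is.null(spots) && nrow(spots) > 0) {
    p <- p + ggplot2::geom_point(data = spots,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 shape = 1, colour = "white", size = 4)
  }
  p
}

#' @describeIn roc_auc Plot the ROC curve.
#' @param object A `tf_roc`.
#' @param ... Unused.
#' @export
autoplot.tf_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f (%.3f-%.3f)", object$auc,
                                  object$conf_low, object$conf_high)) +
    ggplot2::theme_minimal()
}

#' @describeIn estimate_tfbut Plot the segment timeline with breakup marks.
#' @param object A `tf_tfbut`.
#' @param ... Unused.
#' @export
autoplot.tf_tfbut <- function(object, ...) {
  seg <- object$segments
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(
      x = 0, xend = .data$end_s - .data$opening_s,
      y = .data$segment, yend = .data$segment), colour = "grey70") +
    ggplot2::geom_point(
      data = seg[!seg$censored, ],
      ggplot2::aes(x = .data$breakup_s, y = .data$segment),
      colour = "red", size = 3) +
    ggplot2::geom_vline(xintercept = object$tfbut_s, linetype = 2) +
    ggplot2::scale_y_reverse(breaks = seg$segment) +
    ggplot2::labs(x = "Seconds after eye opening", y = "Blink segment",
                  title = if (!is.na(object$tfbut_s))
                    sprintf("TFBUT = %.2f s", object$tfbut_s)
                  else sprintf("TFBUT > %.1f s (censored)", object$lower_bound_s)) +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_frames Plot the report's ROC curve.
#' @param object A `tf_eval`.
#' @param ... Unused.
#' @export
autoplot.tf_eval <- function(object, ...) autoplot(object$roc)
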