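#' Plot a FROC curve
#'
#' @param object A `froc_curve`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot froc_curve
#' @export
autoplot.froc_curve <- function(object, ...) {
  pts <- object$points
  pts <- dplyr::bind_rows(tibble::tibble(threshold = Inf, fppi = 0, sensitivity = 0), pts)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fppi, y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::coord_cartesian(xlim = c(0, max(1, max(pts$fppi))), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positives per image (FPPI)", y = "Lesion sensitivity",
      title = sprintf("FROC curve (partial AUC over FPPI in (0,1): %.1f%%)",
                      object$auc_percent)
    ) +
    ggplot2::theme_minimal()
}

#' Plot translator training losses
#'
#' @param object A `density_translator`.
#' @param ... Ignored.
#' @return A ggplot of the loss components per iteration.
#' @method autoplot density_translator
#' @export
autoplot.density_translator <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"iteration",
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Iteration", y = "Loss",
                  title = "Translator training losses") +
    ggplot2::theme_minimal()
}

#' Plot a Frechet-distance bounds report
#'
#' @param object A `fid_bounds_report`.
#' @param ... Ignored.
#' @return A ggplot showing the synthetic set's distance against its bounds.
#' @method autoplot fid_bounds_report
#' @export
autoplot.fid_bounds_report <- function(object, ...) {
  df <- tidy.fid_bounds_report(object)
  df$bound <- factor(df$bound, levels = c("lower", "value", "upper"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bound, y = .data$fid)) +
    ggplot2::geom_col(fill = c("grey70", if (object$in_bounds) "seagreen" else "firebrick", "grey70")) +
    ggplot2::labs(x = NULL, y = "Frechet distance",
                  title = sprintf("Synthetic set %s bounds",
                                  if (object$in_bounds) "within" else "outside")) +
    ggplot2::theme_minimal()
}

#' Display a phantom record with its lesion boxes
#'
#' @param record One-row manifest tibble.
#' @return A ggplot raster of the image with lesion boxes overlaid.
#' @export
plot_phantom <- function(record) {
  img <- record$image[[1]]
  df <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$value <- as.vector(t(img))[(df$y - 1) * ncol(img) + df$x]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s  (%s view, BI-RADS %s, %.0f%% dense)",
                                  record$id, record$view, record$birads,
                                  record$density_percent),
                  x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_void()
  les <- record$lesions[[1]]
  if (!is.null(les) && nrow(les) > 0) {
    p <- p + ggplot2::geom_rect(
      data = les,
      ggplot2::aes(xmin = .data$x + 1, xmax = .data$x + .data$w,
                   ymin = .data$y + 1, ymax = .data$y + .data$h),
      inherit.aes = FALSE, colour = "red", fill = NA, linewidth = 0.4
    )
  }
  p
}
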