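# ggplot2 visualization methods for the main result types.

mat_to_df <- function(m, value_name = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Plot a phantom study
#'
#' Gray image with optional mask contours.
#'
#' @param object A `cxr_phantom_study`.
#' @param masks Draw lung/heart mask outlines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cxr_phantom_study <- function(object, masks = TRUE, ...) {
  df <- mat_to_df(object$image)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "gray")
  if (masks) {
    for (m in list(object$lung_mask, object$heart_mask)) {
      dm <- mat_to_df(m)
      g <- g + ggplot2::geom_contour(
        data = dm,
        ggplot2::aes(x = .data$col, y = -.data$row, z = .data$value),
        breaks = 0.5, colour = "cyan", linewidth = 0.3, inherit.aes = FALSE
      )
    }
  }
  g
}

#' Plot a Grad-CAM map or aligned saliency
#'
#' @param object A `cxr_gradcam` or `cxr_aligned_saliency`.
#' @param image Optional underlying gray image for context.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cxr_gradcam <- function(object, image = NULL, ...) {
  plot_heatmap(object$heatmap, image)
}

#' @rdname autoplot.cxr_gradcam
#' @export
autoplot.cxr_aligned_saliency <- function(object, image = NULL, ...) {
  plot_heatmap(object$aligned_map, image)
}

plot_heatmap <- function(heat, image = NULL) {
  df <- mat_to_df(heat)
  g <- ggplot2::ggplot()
  if (!is.null(image)) {
    if (!all(dim(image) == dim(heat))) {
      image <- resize_bilinear(image, nrow(heat), ncol(heat))
    }
    di <- mat_to_df(image)
    g <- g + ggplot2::geom_raster(
      data = di, ggplot2::aes(x = .data$col, y = -.data$row, alpha = .data$value),
      fill = "grey20"
    ) + ggplot2::scale_alpha_continuous(range = c(0, 1), guide = "none")
  }
  g + ggplot2::geom_raster(
    data = df, ggplot2::aes(x = .data$col, y = -.data$row, fill = .data$value),
    alpha = 0.55
  ) +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "activation")
}

#' Plot an evaluation table
#'
#' Per-class AUROC bars with the macro average marked.
#'
#' @param object A `cxr_eval` tibble from [classification_metrics()].
#' @param metric Column to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cxr_eval <- function(object, metric = "auroc", ...) {
  per <- dplyr::filter(object, !.data$class %in% c("macro", "micro"))
  macro <- dplyr::filter(object, .data$class == "macro")[[metric]]
  ggplot2::ggplot(per, ggplot2::aes(
    x = stats::reorder(.data$class, .data[[metric]]), y = .data[[metric]]
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = macro, linetype = 2, colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = metric,
                  subtitle = sprintf("macro %s = %.3f", metric, macro)) +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' @param object A `cxr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cxr_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' @export
print.cxr_report <- function(x, ...) {
  cat(sprintf("Diagnostic report (%d finding%s)\n", length(x$findings),
              if (length(x$findings) == 1) "" else "s"))
  for (f in x$findings) {
    cat(sprintf("  %-20s p = %.3f  [%s]\n    %s\n", f$disease_label,
                f$probability, f$region, f$text))
  }
  invisible(x)
}

#' @export
print.cxr_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "cxrreason fit: preset '%s', %d parameters, %d epochs (best %d, val micro-AUROC %.3f)\n",
    g$preset, g$n_params, g$epochs, g$best_epoch, g$best_val_micro_auroc
  ))
  invisible(x)
}
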