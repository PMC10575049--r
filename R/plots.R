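#' Plot an iPM image
#'
#' Raster plot of a single interference image with a diverging palette
#' centred at zero (the background level after spatial-difference
#' subtraction); optionally overlays scatterer locations.
#'
#' @param image Numeric matrix.
#' @param scene Optional [scatterers()] tibble to overlay.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_ipm_image <- function(image, scene = NULL, title = NULL) {
  df <- tibble::tibble(
    x = rep(0:(ncol(image) - 1), each = nrow(image)),
    y = rep(0:(nrow(image) - 1), times = ncol(image)),
    value = as.vector(unclass(image))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", midpoint = 0) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "x (px)", y = "y (px)",
                  fill = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(scene) && nrow(scene) > 0) {
    p <- p + ggplot2::geom_point(
      data = scene, ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, shape = 3, colour = "black", size = 2
    )
  }
  p
}

#' Loss curves of a fitted Y-Net
#'
#' Train/validation curves of the four loss components and their weighted
#' total, on a log scale, with the best epoch marked.
#'
#' @param object A `ynet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ynet_fit
#' @export
autoplot.ynet_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_minimal()
}

#' Input vs. reconstruction comparison plot
#'
#' @param object An `ipm_reconstruction` (with an input image attached).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ipm_reconstruction
#' @export
autoplot.ipm_reconstruction <- function(object, ...) {
  panels <- list(reconstruction = object$image)
  if (!is.null(object$input)) panels <- c(list(input = object$input), panels)
  df <- dplyr::bind_rows(lapply(names(panels), function(nm) {
    m <- panels[[nm]]
    tibble::tibble(
      panel = nm,
      x = rep(0:(ncol(m) - 1), each = nrow(m)),
      y = rep(0:(nrow(m) - 1), times = ncol(m)),
      value = as.vector(unclass(m))
    )
  }))
  df$panel <- factor(df$panel, levels = c("input", "reconstruction"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", midpoint = 0) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "intensity") +
    ggplot2::theme_minimal()
}
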