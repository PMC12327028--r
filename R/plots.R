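#' Plot longitudinal vessel-parameter series
#'
#' Line-and-point plot of each parameter over time, faceted by parameter
#' (free y scales) and coloured by dimensionality (3D vs en face 2D).
#' Works directly on the output of [vessel_metrics()] rows bound across
#' days, or on [ad_timecourse()].
#'
#' @param data tibble with columns `day`, `dims`, `parameter`, `value`.
#' @return a ggplot object.
#' @export
plot_longitudinal <- function(data) {
  stopifnot(all(c("day", "dims", "parameter", "value") %in% names(data)))
  ggplot2::ggplot(data, ggplot2::aes(.data$day, .data$value,
                                     colour = .data$dims)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "day", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a layer thickness map
#'
#' En face heat map of per-column layer thickness in micrometres.
#'
#' @param x a `thickness_map` from [thickness_stats()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_thickness_map <- function(x, ...) {
  stopifnot(inherits(x, "thickness_map"))
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$thickness_um)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "µm") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(x$layer, "thickness"), x = "x (fast)",
                  y = "y (slow)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_thickness_map
#' @importFrom ggplot2 autoplot
#' @export
autoplot.thickness_map <- function(x, ...) plot_thickness_map(x, ...)

#' Plot training curves of a segmentation model
#'
#' @param model a `unet_model` from [train_unet()].
#' @return a ggplot object (train/validation loss per epoch and fold).
#' @export
plot_training_curves <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  df <- tidyr::pivot_longer(model$curves, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  df <- dplyr::filter(df, is.finite(.data$loss))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$series,
                                   group = interaction(.data$fold,
                                                       .data$series))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
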