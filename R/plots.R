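#' Plot parameter maps
#'
#' Side-by-side images of the estimated hemoglobin concentration and
#' scattering power; invalid pixels are blanked.
#'
#' @param object A `parameter_maps` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parameter_maps <- function(object, ...) {
  df <- as_tibble.parameter_maps(object)
  df <- tidyr::pivot_longer(df, c("cth", "b"), names_to = "parameter")
  df$value[!df$valid] <- NA
  df$parameter <- factor(df$parameter, c("cth", "b"),
                         c("C[th]~('vol.%')", "b"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~parameter, labeller = ggplot2::label_parsed) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}

#' Plot relative-change time courses
#'
#' @param tc Output of [relative_change()].
#' @return A ggplot object with one panel per quantity.
#' @export
plot_timecourse <- function(tc) {
  df <- tidyr::pivot_longer(tc, c("delta_cth_pct", "delta_b_pct"),
                            names_to = "quantity")
  df$quantity <- factor(df$quantity, c("delta_cth_pct", "delta_b_pct"),
                        c("Delta*C[th]~'%'", "Delta*b~'%'"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$roi)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::label_parsed) +
    ggplot2::labs(x = "week", y = "relative change (%)", colour = "ROI")
}

#' Plot estimated against given phantom values
#'
#' Scatter of estimated versus generating values for the phantom validation
#' set, one panel per parameter, with the identity line.
#'
#' @param est Output of [estimate_phantoms()].
#' @return A ggplot object.
#' @export
plot_phantom_validation <- function(est) {
  df <- dplyr::bind_rows(
    tibble::tibble(parameter = "C[th]~('vol.%')", given = est$cth,
                   estimated = est$cth_est),
    tibble::tibble(parameter = "b", given = est$b, estimated = est$b_est)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$given, y = .data$estimated)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free",
                        labeller = ggplot2::label_parsed) +
    ggplot2::labs(x = "given value", y = "estimated value")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
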