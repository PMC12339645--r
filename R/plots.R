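#' Plot a cumulative DVH
#'
#' @param object A `dvh_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dvh_curve
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$dose, y = .data$volume_pct)) +
    geom_line(linewidth = 0.7, colour = "#2c7fb8") +
    labs(x = "Dose (Gy)", y = "Volume (%)",
         title = "Cumulative dose-volume histogram") +
    theme_minimal()
}

#' Plot an ROI CT-number histogram
#'
#' Bar histogram of pixel CT numbers inside a region of interest, the view
#' used to compare a plug's spread against real tissue.
#'
#' @param object An `roi_statistics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roi_statistics
#' @export
autoplot.roi_statistics <- function(object, ...) {
  h <- object$histogram
  ggplot(h, aes(x = (.data$bin_left + .data$bin_right) / 2, y = .data$count)) +
    geom_col(width = h$bin_right[1] - h$bin_left[1], fill = "#41ab5d",
             colour = "grey30", linewidth = 0.2) +
    geom_vline(xintercept = object$mean_hu, linetype = 2) +
    labs(x = "CT number (HU)", y = "Pixel count",
         title = sprintf("ROI histogram: mean %.1f HU, SD %.1f HU (n = %d)",
                         object$mean_hu, object$sd_hu, object$n)) +
    theme_minimal()
}

#' Plot a CT-RED/MD conversion table
#'
#' Knots and the piecewise-linear interpolant for both the relative electron
#' density and mass density branches.
#'
#' @param object A `ct_conversion_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ct_conversion_table
#' @export
autoplot.ct_conversion_table <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("red", "md"),
                              names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity, c("red", "md"),
                          c("Relative electron density", "Mass density (g/cm3)"))
  ggplot(long, aes(x = .data$hu, y = .data$value)) +
    geom_line(colour = "grey50") +
    geom_point(aes(colour = !is.na(.data$material) & .data$material != "")) +
    facet_wrap(~quantity, scales = "free_y") +
    scale_colour_manual(values = c("FALSE" = "black", "TRUE" = "#d95f02"),
                        guide = "none") +
    labs(x = "CT number (HU)", y = NULL,
         title = sprintf("CT-RED/MD conversion table (%s)",
                         table_variant(object))) +
    theme_minimal()
}
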