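#' Area-versus-CII classification plot
#'
#' The diagnostic dot plot of the morphometric gating: each cell at its
#' (area, CII) coordinate, colored by class, with the control-derived area
#' band and irregularity cutoff drawn as dashed lines.
#'
#' @param cells Classified cells from [classify_cells()].
#' @param thresholds The [derive_thresholds()] object used to classify.
#' @return A ggplot object.
#' @export
plot_classification <- function(cells, thresholds) {
  check_df_cols(cells, c("area", "cii", "class"))
  ggplot2::ggplot(cells, ggplot2::aes(.data$area, .data$cii,
                                      color = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_vline(xintercept = c(thresholds$area_low,
                                       thresholds$area_high),
                        linetype = "dashed", color = "grey40") +
    ggplot2::geom_hline(yintercept = thresholds$cii_high,
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = expression(Area ~ (mu * m^2)),
                  y = "Cardiomyocyte irregularity index",
                  color = "Class") +
    ggplot2::theme_minimal()
}

#' Group-summary plot with significance letters
#'
#' Per-variable panels of group locations (mean or median, per the route)
#' with spread bars and the compact-letter annotations above each group —
#' groups sharing a letter are not significantly different.
#'
#' @param object A `chp_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chp_comparison
#' @export
autoplot.chp_comparison <- function(object, ...) {
  df <- purrr::pmap(
    list(object$variable, object$summaries, object$letters),
    function(v, s, lt) dplyr::mutate(s, variable = v, letter = lt[.data$group])
  ) |>
    dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$location)) +
    ggplot2::geom_col(fill = "grey75", color = "grey30", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$spread_low,
                                        ymax = .data$spread_high),
                           width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(y = .data$spread_high, label = .data$letter),
                       vjust = -0.6) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Group summary") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Display a synthetic field
#'
#' @param x A `cell_field` or `collagen_field`.
#' @param ... Passed to [graphics::rasterImage()] via EBImage display.
#' @export
plot.cell_field <- function(x, ...) {
  EBImage::display(EBImage::Image(aperm(x$image, c(2, 1, 3)),
                                  colormode = "Color"), method = "raster", ...)
  invisible(x)
}

#' @rdname plot.cell_field
#' @export
plot.collagen_field <- plot.cell_field
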