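# ggplot2 views of the main result types.

#' Map one layer of a cube
#'
#' @param object a cube.
#' @param field field name to map (default `"red"` or the first 3-d field).
#' @param index time-step index to show.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lcspp_cube
#' @export
autoplot.lcspp_cube <- function(object, field = NULL, index = 1, ...) {
  fields3 <- purrr::keep(cube_fields(object), function(nm)
    is.array(object[[nm]]) && length(dim(object[[nm]])) == 3L)
  field <- field %||% fields3[1]
  d <- tidyr::expand_grid(lon = object$grid$lon, lat = object$grid$lat)
  d$value <- as.vector(object[[field]][, , index])
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, %s", field,
                                  period_label(object$time)[index]),
                  fill = field)
}

#' Plot pseudo-invariant site diagnostics
#'
#' Annual detrended normalized anomalies per band, with the +/- 1 percent
#' band the calibrated record is expected to stay within.
#'
#' @param object a [pics_diagnostics()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pics_diagnostics
#' @export
autoplot.pics_diagnostics <- function(object, ...) {
  ggplot2::ggplot(object$anomalies,
                  ggplot2::aes(.data$year, .data$anomaly_pct,
                               colour = .data$band)) +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "detrended normalized anomaly (%)", x = NULL)
}

#' Plot the emulator hyperparameter search
#'
#' @param object a `sif_emulator`.
#' @param ... unused.
#' @return a ggplot of validation NSE across the grid.
#' @method autoplot sif_emulator
#' @export
autoplot.sif_emulator <- function(object, ...) {
  d <- object$scores
  d$depth <- factor(d$layers)
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$width), .data$val_nse,
                                  colour = .data$depth,
                                  shape = factor(.data$lr))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "hidden width", y = "validation NSE",
                  colour = "hidden layers", shape = "learning rate")
}
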