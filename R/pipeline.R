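#' Run the full harmonization and cross-calibration chain on a scene
#'
#' Convenience wrapper tying the stages together in the order the record
#' is processed: PICS bias proxy, per-pixel SZA/bias regression and
#' removal, windowed linear calibration against the reference stream over
#' the overlap era, residual-network correction on environmental
#' covariates, and (optionally) seasonal-mean + HANTS gap-filling.
#'
#' @param scene an [simulate_scene()] result (biweekly cadence), or any
#'   list with `drifting`, `reference`, `met` cubes and an `epochs` table.
#' @param pics_calibration linear pixel indices of the calibration PICS
#'   set (default: the calibration half of the scene truth's PICS pixels).
#' @param window window width for [fit_windowed_linear()].
#' @param residual_hidden hidden layer of the residual net; `NULL` skips
#'   the residual stage.
#' @param residual_epochs training epochs for the residual net.
#' @param gap_fill run [seasonal_mean_fill()] + [hants_gapfill()] on the
#'   calibrated record.
#' @param seed integer seed (residual-net initialization).
#' @return an `lcref_calibration` list with the intermediate and final
#'   cubes (`harmonized`, `linear`, `calibrated`) and the fitted model
#'   objects (`pics_bias`, `sza_model`, `lin`, `residual`).
#' @export
calibrate_record <- function(scene, pics_calibration = NULL, window = 5,
                             residual_hidden = 32, residual_epochs = 400,
                             gap_fill = FALSE, seed = 1) {
  if (is.null(pics_calibration)) {
    check_that(!is.null(scene$truth), "pics_calibration required without truth")
    pics_calibration <- pics_sets(scene$truth)$calibration
  }
  epochs <- scene$epochs
  pb <- compute_pics_bias(scene$drifting, pics_calibration, epochs)
  szm <- fit_sza_bias_model(scene$drifting, pb, scene$met)
  harmonized <- remove_sza_bias(scene$drifting, szm, pb, epochs)

  lin <- fit_windowed_linear(harmonized, scene$reference, window = window,
                             epochs = epochs)
  linear <- apply_windowed_linear(harmonized, lin)

  residual <- NULL
  calibrated <- linear
  if (!is.null(residual_hidden)) {
    gam <- compute_residual(linear, scene$reference)
    residual <- train_residual_model(gam, scene$met, linear,
                                     hidden = residual_hidden,
                                     epochs = residual_epochs, seed = seed)
    calibrated <- apply_double_calibration(harmonized, lin, residual,
                                           scene$met)
  }
  if (gap_fill) calibrated <- hants_gapfill(seasonal_mean_fill(calibrated))

  structure(list(harmonized = harmonized, linear = linear,
                 calibrated = calibrated, pics_bias = pb, sza_model = szm,
                 lin = lin, residual = residual, epochs = epochs,
                 pics_calibration = pics_calibration),
            class = "lcref_calibration")
}

#' @export
print.lcref_calibration <- function(x, ...) {
  cat("<lcref_calibration>\n")
  cat(sprintf("  record: %d periods, %d x %d pixels\n",
              nrow(x$calibrated$time), grid_dim(x$calibrated$grid)[1],
              grid_dim(x$calibrated$grid)[2]))
  if (!is.null(x$residual))
    cat(sprintf("  residual net validation RMSE: red %.4g, nir %.4g\n",
                x$residual$validation$rmse[1], x$residual$validation$rmse[2]))
  invisible(x)
}

#' @describeIn calibrate_record glance method: overlap-era RMSE against the
#'   reference stream for the raw, harmonized, linear and fully calibrated
#'   stages (requires the scene to be attached via the `scene` argument).
#' @param x an `lcref_calibration`.
#' @param scene the scene the calibration was fitted on.
#' @param ... unused.
#' @method glance lcref_calibration
#' @export
glance.lcref_calibration <- function(x, scene, ...) {
  ov <- overlap_steps(x$calibrated, scene$reference)
  stage_rmse <- function(cube, band)
    rmse(as.vector(cube[[band]][, , ov]),
         as.vector(scene$reference[[band]][, , ov]))
  stages <- list(raw = scene$drifting, harmonized = x$harmonized,
                 linear = x$linear, calibrated = x$calibrated)
  purrr::map_dfr(names(stages), function(nm) {
    tibble::tibble(stage = nm,
                   rmse_red = stage_rmse(stages[[nm]], "red"),
                   rmse_nir = stage_rmse(stages[[nm]], "nir"))
  })
}
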