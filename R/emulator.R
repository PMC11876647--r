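# SIF emulation: grid soundings, split, hyperparameter search, predict.

#' Aggregate SIF soundings to daily grid cells
#'
#' Soundings are first screened to best-quality, clear-sky, nadir-mode
#' retrievals, then averaged per grid cell and day. Cells with fewer than
#' `min_soundings` retrievals are dropped (aggregation reduces the random
#' retrieval noise by `1/sqrt(n)`, and low-n cells would dominate the
#' target noise). Drop counts are attached as attribute `"dropped_cells"`.
#'
#' @param table a sounding tibble ([simulate_soundings()] layout: `cell`,
#'   `date`, `sif_757`, `sza`, `quality_flag`, `mode`, `cloud_flag`, and
#'   matched `red`/`nir`).
#' @param min_soundings minimum soundings per cell-day (default 5).
#' @return a tibble of gridded samples: `cell`, `date`, `year`, `sif`
#'   (cell mean), `n_soundings`, `cos_sza` (cell mean), `red`, `nir`.
#' @export
grid_soundings <- function(table, min_soundings = 5) {
  screened <- dplyr::filter(table, .data$quality_flag == 0L,
                            .data$mode == "nadir", .data$cloud_flag == 0L)
  cells <- screened |>
    dplyr::group_by(.data$cell, .data$date) |>
    dplyr::summarise(sif = mean(.data$sif_757),
                     n_soundings = dplyr::n(),
                     cos_sza = mean(cos(.data$sza * pi / 180)),
                     red = mean(.data$red), nir = mean(.data$nir),
                     .groups = "drop")
  kept <- dplyr::filter(cells, .data$n_soundings >= min_soundings)
  kept$year <- as.integer(format(kept$date, "%Y"))
  attr(kept, "dropped_cells") <- nrow(cells) - nrow(kept)
  kept
}

#' Train/validation/test split by year blocks
#'
#' Test samples are all samples in `test_years` (kept outside the training
#' span to avoid temporal-autocorrelation leakage); a seeded random
#' `val_fraction` of the training-year samples becomes the validation set.
#'
#' @param samples a gridded-sample tibble with a `year` column.
#' @param train_years,test_years disjoint integer year sets.
#' @param val_fraction fraction of training-year samples held out
#'   (default 0.2; the draw is exact: `round(n * val_fraction)` rows).
#' @param seed integer seed.
#' @return list with tibbles `train`, `val`, `test`.
#' @export
split_samples <- function(samples, train_years, test_years,
                          val_fraction = 0.2, seed = 1) {
  check_that(length(intersect(train_years, test_years)) == 0,
             "train and test years must be disjoint")
  test <- dplyr::filter(samples, .data$year %in% test_years)
  pool <- dplyr::filter(samples, .data$year %in% train_years)
  check_that(nrow(pool) > 0 && nrow(test) > 0, "empty split")
  n_val <- round(nrow(pool) * val_fraction)
  idx <- with_seed(seed, sample.int(nrow(pool), n_val))
  list(train = pool[-idx, , drop = FALSE], val = pool[idx, , drop = FALSE],
       test = test)
}

emulator_features <- function(d) {
  cbind(red = d$red, nir = d$nir, cos_sza = d$cos_sza)
}

#' Train the SIF emulator with a hyperparameter grid search
#'
#' Feedforward networks mapping (red, NIR, cos SZA) to gridded SIF. Every
#' combination of learning rate, depth and width is trained for a fixed
#' number of epochs (no dropout or early stopping); the combination with
#' the best validation Nash-Sutcliffe efficiency is retrained on the
#' training and validation data combined and returned.
#'
#' @param train,val tibbles from [split_samples()] with columns `red`,
#'   `nir`, `cos_sza`, `sif`.
#' @param grid hyperparameter grid: list with `lr`, `layers`, `width`
#'   (defaults: learning rates 0.001 and 0.0005, 1-3 hidden layers of
#'   8, 32 or 64 units).
#' @param epochs training epochs (default 40).
#' @param batch_size mini-batch size (default 256).
#' @param seed integer seed.
#' @return a `sif_emulator`: the final network, the feature order, and the
#'   full grid of validation scores (`$scores`).
#' @export
train_emulator <- function(train, val,
                           grid = list(lr = c(0.001, 0.0005),
                                       layers = 1:3,
                                       width = c(8, 32, 64)),
                           epochs = 40, batch_size = 256, seed = 1) {
  check_that(nrow(train) > 0 && nrow(val) > 0, "empty training split")
  xtr <- emulator_features(train); ytr <- train$sif
  xva <- emulator_features(val); yva <- val$sif

  combos <- tidyr::expand_grid(lr = grid$lr, layers = grid$layers,
                               width = grid$width)
  scores <- combos
  scores$val_nse <- NA_real_
  scores$val_rmse <- NA_real_
  scores$failed <- FALSE
  best <- NULL; best_nse <- -Inf
  for (i in seq_len(nrow(combos))) {
    hid <- rep(combos$width[i], combos$layers[i])
    m <- mlp_fit(xtr, ytr, hidden = hid, lr = combos$lr[i], epochs = epochs,
                 batch_size = batch_size, seed = seed + i)
    pv <- mlp_predict(m, xva)
    if (any(!is.finite(pv))) { scores$failed[i] <- TRUE; next }
    scores$val_nse[i] <- nse(pv, yva)
    scores$val_rmse[i] <- rmse(pv, yva)
    if (scores$val_nse[i] > best_nse) { best_nse <- scores$val_nse[i]; best <- i }
  }
  check_that(!is.null(best), "all hyperparameter combinations diverged")
  hid <- rep(combos$width[best], combos$layers[best])
  final <- mlp_fit(rbind(xtr, xva), c(ytr, yva), hidden = hid,
                   lr = combos$lr[best], epochs = epochs,
                   batch_size = batch_size, seed = seed + best)
  ptr <- mlp_predict(final, rbind(xtr, xva))
  structure(list(net = final, features = c("red", "nir", "cos_sza"),
                 scores = scores, best = combos[best, ],
                 train_nse = nse(ptr, c(ytr, yva)),
                 train_rmse = rmse(ptr, c(ytr, yva))),
            class = "sif_emulator")
}

#' Predict SIF from reflectance and solar geometry
#'
#' Standardized forward pass of the trained emulator. Reflectance outside
#' `[0, 1]` is clipped with a warning; cells with `cos_sza <= 0`
#' (high-latitude winter, sun below horizon at overpass) get 0.
#'
#' @param model a [train_emulator()] result.
#' @param red,nir reflectance, 0-1.
#' @param cos_sza cosine of the solar zenith angle at the observation.
#' @return SIF estimates, mW m-2 nm-1 sr-1.
#' @export
predict_sif <- function(model, red, nir, cos_sza) {
  n_out <- sum(red < 0 | red > 1 | nir < 0 | nir > 1, na.rm = TRUE)
  if (n_out > 0) {
    warn(sprintf("%d reflectance values outside [0, 1] were clipped", n_out))
    red <- pmin(pmax(red, 0), 1)
    nir <- pmin(pmax(nir, 0), 1)
  }
  out <- mlp_predict(model$net,
                     cbind(red = red, nir = nir, cos_sza = pmax(cos_sza, 0)))
  out[cos_sza <= 0] <- 0
  out
}

#' @export
print.sif_emulator <- function(x, ...) {
  cat(sprintf("<sif_emulator> best: lr %.4g, %d x %d; train NSE %.3f\n",
              x$best$lr, x$best$layers, x$best$width, x$train_nse))
  invisible(x)
}

#' @describeIn train_emulator tidy method: one row per hyperparameter
#'   combination with its validation scores.
#' @param x a `sif_emulator`.
#' @param ... unused.
#' @method tidy sif_emulator
#' @export
tidy.sif_emulator <- function(x, ...) x$scores

#' @describeIn train_emulator glance method: the selected combination and
#'   its training-set scores.
#' @method glance sif_emulator
#' @export
glance.sif_emulator <- function(x, ...) {
  tibble::tibble(lr = x$best$lr, layers = x$best$layers,
                 width = x$best$width,
                 val_nse = max(x$scores$val_nse, na.rm = TRUE),
                 train_nse = x$train_nse, train_rmse = x$train_rmse)
}
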