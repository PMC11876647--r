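#' Fit a small feedforward neural network
#'
#' A fully-connected multilayer perceptron with ReLU hidden activations and
#' a linear output, trained on mean squared error with the Adam optimizer
#' and seeded He-style initialization. Inputs (and, internally, targets)
#' are standardized using moments frozen from the training data;
#' predictions are returned in original units. This is the workhorse behind
#' [train_residual_model()] and [train_emulator()].
#'
#' @param x numeric matrix of predictors (n x p); rows with non-finite
#'   values are dropped (count recorded in the training log).
#' @param y numeric vector or matrix of targets (n x q).
#' @param hidden integer vector of hidden-layer sizes, e.g. `c(32)` or
#'   `c(64, 64, 64)`.
#' @param lr Adam learning rate.
#' @param epochs number of passes over the training data.
#' @param batch_size mini-batch size; `Inf` for full-batch training.
#' @param seed integer seed for initialization and shuffling.
#' @param x_val,y_val optional validation split; per-epoch validation loss
#'   is recorded when given.
#' @return an object of class `lcspp_mlp` with the weights, the frozen
#'   standardization parameters and a training log.
#' @export
mlp_fit <- function(x, y, hidden = c(32), lr = 1e-3, epochs = 40,
                    batch_size = 256, seed = 1, x_val = NULL, y_val = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  keep <- complete.cases(x) & complete.cases(y) &
    rowSums(!is.finite(x)) == 0 & rowSums(!is.finite(y)) == 0
  dropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
  check_that(nrow(x) >= 2, "need at least 2 complete training rows")

  xm <- colMeans(x); xs <- apply(x, 2, sd); xs[xs == 0 | !is.finite(xs)] <- 1
  ym <- colMeans(y); ys <- apply(y, 2, sd); ys[ys == 0 | !is.finite(ys)] <- 1
  xt <- sweep(sweep(x, 2, xm), 2, xs, "/")
  yt <- sweep(sweep(y, 2, ym), 2, ys, "/")

  sizes <- c(ncol(x), hidden, ncol(y))
  nl <- length(sizes) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(nl), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(nl), function(l) rep(0, sizes[l + 1]))

    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0

    n <- nrow(xt)
    bs <- if (!is.finite(batch_size)) n else min(batch_size, n)
    log_loss <- numeric(epochs)
    log_val <- rep(NA_real_, epochs)

    forward <- function(X) {
      acts <- vector("list", nl + 1L); acts[[1]] <- X
      for (l in seq_len(nl)) {
        z <- sweep(acts[[l]] %*% W[[l]], 2, b[[l]], "+")
        acts[[l + 1]] <- if (l < nl) pmax(z, 0) else z
      }
      acts
    }

    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = bs)) {
        rows <- ord[start:min(start + bs - 1, n)]
        acts <- forward(xt[rows, , drop = FALSE])
        pred <- acts[[nl + 1]]
        err <- pred - yt[rows, , drop = FALSE]
        m <- length(rows)
        ep_loss <- ep_loss + mean(err^2); nb <- nb + 1
        delta <- 2 * err / (m * ncol(err))
        for (l in rev(seq_len(nl))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
          }
          t_step <- t_step + 1
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          cor1 <- 1 - beta1^t_step; cor2 <- 1 - beta2^t_step
          W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + eps)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + eps)
        }
      }
      log_loss[ep] <- ep_loss / nb
      if (!is.null(x_val)) {
        model_now <- structure(list(W = W, b = b, xm = xm, xs = xs,
                                    ym = ym, ys = ys, hidden = hidden),
                               class = "lcspp_mlp")
        pv <- mlp_predict(model_now, x_val)
        log_val[ep] <- mean((as.matrix(pv) - as.matrix(y_val))^2, na.rm = TRUE)
      }
    }
  })

  structure(list(W = W, b = b, xm = xm, xs = xs, ym = ym, ys = ys,
                 hidden = hidden,
                 log = tibble::tibble(epoch = seq_len(epochs),
                                      train_mse = log_loss,
                                      val_mse = log_val),
                 dropped_rows = dropped,
                 config = list(lr = lr, epochs = epochs,
                               batch_size = batch_size, seed = seed)),
            class = "lcspp_mlp")
}

#' Predict from a fitted network
#'
#' @param model an `lcspp_mlp`.
#' @param x predictor matrix with the training column order.
#' @return numeric matrix of predictions (n x q) in original target units;
#'   a vector if the network has a single output.
#' @export
mlp_predict <- function(model, x) {
  x <- as.matrix(x)
  xt <- sweep(sweep(x, 2, model$xm), 2, model$xs, "/")
  xt[!is.finite(xt)] <- 0
  nl <- length(model$W)
  a <- xt
  for (l in seq_len(nl)) {
    z <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    a <- if (l < nl) pmax(z, 0) else z
  }
  out <- sweep(sweep(a, 2, model$ys, "*"), 2, model$ym, "+")
  if (ncol(out) == 1L) as.vector(out) else out
}

#' @export
print.lcspp_mlp <- function(x, ...) {
  cat(sprintf("<lcspp_mlp> %d -> %s -> %d; final train MSE %.3g\n",
              length(x$xm), paste(x$hidden, collapse = "-"), length(x$ym),
              tail(x$log$train_mse, 1)))
  invisible(x)
}
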