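# Internal helpers shared across modules.

# stopifnot() with a formatted message
check_that <- function(ok, ..., class = "lcspp_error") {
  if (!isTRUE(ok)) abort(paste0(...), class = class)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# fraction of finite values in an array
finite_frac <- function(x) mean(is.finite(x))

# Batched ordinary least squares over many small regressions sharing a
# common sample dimension.  `y` is an n x m matrix (m independent fits) and
# `xs` a list of p matrices, each n x m (or n-vectors recycled across fits).
# Returns list(coef = p x m, n = m, r2 = m).  Rows with non-finite y or x are
# dropped per fit; fits with fewer than `min_n` usable rows, or with a
# rank-deficient cross-product, yield NA coefficients.
batched_ols <- function(y, xs, min_n = length(xs) + 2L) {
  n <- nrow(y); m <- ncol(y); p <- length(xs)
  xs <- lapply(xs, function(x) {
    if (is.matrix(x)) x else matrix(x, n, m)
  })
  ok <- is.finite(y)
  for (x in xs) ok <- ok & is.finite(x)
  yv <- ifelse(ok, y, 0)
  xv <- lapply(xs, function(x) ifelse(ok, x, 0))
  nn <- colSums(ok)

  xtx <- array(0, c(p, p, m))
  xty <- matrix(0, p, m)
  for (i in seq_len(p)) {
    xty[i, ] <- colSums(xv[[i]] * yv)
    for (j in i:p) {
      s <- colSums(xv[[i]] * xv[[j]])
      xtx[i, j, ] <- s
      xtx[j, i, ] <- s
    }
  }

  coefs <- matrix(NA_real_, p, m)
  r2 <- rep(NA_real_, m)
  syy <- colSums(yv^2)
  sy <- colSums(yv)
  for (k in seq_len(m)) {
    if (nn[k] < min_n) next
    a <- xtx[, , k, drop = TRUE]
    dim(a) <- c(p, p)
    b <- tryCatch(solve(a, xty[, k]), error = function(e) NULL)
    if (is.null(b)) next
    coefs[, k] <- b
    sse <- syy[k] - sum(b * xty[, k])
    sst <- syy[k] - sy[k]^2 / nn[k]
    r2[k] <- if (sst > 0) max(0, 1 - sse / sst) else NA_real_
  }
  list(coef = coefs, n = nn, r2 = r2)
}

# seeded RNG scope: evaluates expr with a local RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}
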