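# Internal helpers shared across modules.

# Run `code` under a fixed RNG state without disturbing the caller's stream.
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' All stages of an experiment draw their seeds from one master seed through
#' this fixed affine-modular map, so any stage can be reproduced in isolation.
#'
#' @param master master seed (integer).
#' @param offset stage offset (integer; distinct per stage/subject/member).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) %% 2147483647 * 7919 + as.numeric(offset) * 104729) %% 2147483629)
}

# Moore-Penrose pseudoinverse via SVD (tolerance relative to largest
# singular value, as in MASS::ginv but returning the rank as an attribute).
pinv <- function(X, tol = sqrt(.Machine$double.eps)) {
  X <- as.matrix(X)
  s <- svd(X)
  keep <- s$d > tol * max(s$d[1L], .Machine$double.xmin)
  r <- sum(keep)
  out <- if (r == 0L) matrix(0, ncol(X), nrow(X))
  else s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
  attr(out, "rank") <- r
  out
}

# Column z-scoring that maps zero-variance columns to all-zero instead of NaN.
zscore_cols <- function(X, tol = 1e-12) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  out <- sweep(X, 2L, mu, "-")
  ok <- sdv > tol
  out[, ok] <- sweep(out[, ok, drop = FALSE], 2L, sdv[ok], "/")
  out[, !ok] <- 0
  attr(out, "constant_columns") <- which(!ok)
  out
}

stopifnot_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be a single integer >= %s", name, min), call. = FALSE)
}
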