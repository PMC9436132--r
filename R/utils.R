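# Internal helpers shared across modules.

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so simulation helpers are pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Linear interpolation on a uniformly sampled table; values outside the grid
# are clamped to the end nodes (callers mask out-of-support points themselves).
lut_interp <- function(x0, step, values, x) {
  n <- length(values)
  t <- (x - x0) / step
  i0 <- floor(t)
  frac <- t - i0
  i0 <- pmin(pmax(i0, 0), n - 2)
  frac <- pmin(pmax(t - i0, 0), 1)
  values[i0 + 1] * (1 - frac) + values[i0 + 2] * frac
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

as_image_matrix <- function(x) {
  if (inherits(x, "phantom_image")) {
    return(x$delta)
  }
  if (is.matrix(x)) {
    return(x)
  }
  stop("expected a matrix or a phantom_image", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
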