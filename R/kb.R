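#' Truncated Kaiser-Bessel series b(x)
#'
#' The five-term positive series
#' \deqn{b(x) = \sum_{m=0}^{4} \frac{1}{m!\,(m+2)!} (x/2)^{2m+3}}
#' used to build the compactly supported Kaiser-Bessel window. The
#' truncation is part of the window definition, not an approximation that is
#' refined elsewhere.
#'
#' @param x Non-negative numeric vector.
#' @return `b(x)`, elementwise.
#' @export
kb_b <- function(x) {
  stopifnot(all(is.finite(x)))
  h <- x / 2
  out <- 0
  for (m in 0:4) {
    out <- out + h^(2 * m + 3) / (factorial(m) * factorial(m + 2))
  }
  out
}

# term-wise derivative of kb_b
kb_b_prime <- function(x) {
  h <- x / 2
  out <- 0
  for (m in 0:4) {
    out <- out + (2 * m + 3) / (2 * factorial(m) * factorial(m + 2)) * h^(2 * m + 2)
  }
  out
}

#' Kaiser-Bessel window
#'
#' Radially symmetric blob profile
#' \deqn{w_{kb}(x) = b(\alpha_{kb}\pi\sqrt{1-(x/w)^2}) / b(\alpha_{kb}\pi)}
#' with compact support `[-w, w]`; even, non-negative, 1 at the center and 0
#' at the support edge.
#'
#' @param x Signed distance from the blob center (mm); values outside the
#'   support return 0.
#' @param alpha_kb Shape parameter (default 3).
#' @param w Support half-width (mm).
#' @return Window values, elementwise.
#' @export
kb_window <- function(x, alpha_kb = 3, w) {
  if (w <= 0) stop("w must be > 0")
  t <- x / w
  q <- sqrt(pmax(0, 1 - t^2))
  val <- kb_b(alpha_kb * pi * q) / kb_b(alpha_kb * pi)
  val[abs(t) > 1] <- 0
  val
}

#' Analytic derivative of the Kaiser-Bessel window
#'
#' Closed-form `d/dx w_kb(x)` obtained by the chain rule through the
#' term-wise differentiated series; odd, zero at the center and outside the
#' support, and finite at the support edge (the series vanishes fast enough
#' to cancel the square-root singularity).
#'
#' @inheritParams kb_window
#' @return Derivative values (1/mm), elementwise.
#' @export
kb_window_derivative <- function(x, alpha_kb = 3, w) {
  if (w <= 0) stop("w must be > 0")
  t <- x / w
  q <- sqrt(pmax(0, 1 - t^2))
  # d/dx = b'(a*pi*q) * a*pi * (-x / (w^2 * q)) / b(a*pi);  b'(u)/q -> 0 as q -> 0
  ratio <- ifelse(q > 0, kb_b_prime(alpha_kb * pi * q) / q, 0)
  val <- -alpha_kb * pi * x / w^2 * ratio / kb_b(alpha_kb * pi)
  val[abs(t) >= 1] <- 0
  val
}

#' Tabulate the Kaiser-Bessel window and its analytic derivative
#'
#' Samples `w_kb` and `d w_kb / dx` on a uniform grid over `[-w, w]`. Queries
#' between nodes use linear interpolation, so the table error decays
#' quadratically in `n_samples`.
#'
#' @param alpha_kb Shape parameter.
#' @param w Support half-width (mm); the projector default is twice the pixel
#'   pitch, so each blob spans multiple classical pixels.
#' @param n_samples Number of table nodes (>= 64).
#' @return A `kb_profile`: the sampled window (`table_w`), its derivative
#'   (`table_dw`), the grid and the window area `integral(w_kb) dx` used by
#'   the operator normalization.
#' @export
build_lookup <- function(alpha_kb = 3, w, n_samples = 2048) {
  if (w <= 0) stop("w must be > 0")
  n_samples <- as.integer(n_samples)
  if (n_samples < 64L) stop("n_samples must be >= 64")
  # odd node count places a node exactly at 0, so the tabulated center value
  # (window 1, derivative 0) is reproduced without interpolation error
  if (n_samples %% 2L == 0L) n_samples <- n_samples + 1L
  x <- seq(-w, w, length.out = n_samples)
  tw <- kb_window(x, alpha_kb, w)
  tdw <- kb_window_derivative(x, alpha_kb, w)
  step <- x[2] - x[1]
  area <- sum((tw[-1] + tw[-n_samples]) / 2) * step
  structure(
    list(
      alpha_kb = alpha_kb, w = w, n_samples = n_samples,
      x = x, step = step, table_w = tw, table_dw = tdw, area = area
    ),
    class = "kb_profile"
  )
}

#' Evaluate a Kaiser-Bessel lookup table
#'
#' Linear interpolation between table nodes; zero outside the support.
#'
#' @param kb A [build_lookup()] profile.
#' @param x Query points (mm).
#' @param derivative If `TRUE`, evaluate the derivative table.
#' @return Interpolated values.
#' @export
kb_lookup <- function(kb, x, derivative = FALSE) {
  stopifnot(inherits(kb, "kb_profile"))
  tab <- if (derivative) kb$table_dw else kb$table_w
  out <- lut_interp(-kb$w, kb$step, tab, x)
  out[abs(x) > kb$w] <- 0
  out
}
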