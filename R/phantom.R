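#' Synthetic breast-like phantom of the refractive-index decrement
#'
#' Generates a piecewise-smooth map of the refractive-index decrement
#' \eqn{\delta}: a smooth elliptical adipose-like background carrying
#' `n_inclusions` non-overlapping elliptical inclusions of contrasting
#' \eqn{\delta}, plus a gentle low-frequency texture. Edges of the support
#' ellipse and of the inclusions are sharp, so at realistic interferometer
#' sensitivity the simulated differential-phase sinograms wrap at the
#' strongest edges. A paired attenuation map `mu` is derived from `delta`
#' by a fixed affine rescaling (attenuation only has to make simulated
#' phase-stepping counts realistic; it is never reconstructed).
#'
#' @param shape Integer vector `(rows, cols)`.
#' @param n_inclusions Number of contrasting inclusions (may be 0).
#' @param seed RNG seed; the phantom is a pure function of the arguments and
#'   this seed.
#' @param delta_range Length-2 numeric `(lo, hi)`, `lo >= 0`: all delta values
#'   lie in this band. The default unit-rescaled band keeps images O(1); the
#'   physical scale (delta about 1e-7) is equivalent through the operator
#'   sensitivity constant.
#' @param mu_coeff Slope of the affine delta -> mu map (1/mm at delta = hi).
#' @param texture_amp Amplitude of the smooth background texture, as a
#'   fraction of the delta range.
#' @return A `phantom_image`: list with matrices `delta`, `mu`, logical
#'   `mask` (support) and the generating arguments.
#' @export
make_breast_phantom <- function(shape,
                                n_inclusions = 5,
                                seed = 1,
                                delta_range = c(0, 1),
                                mu_coeff = 0.02,
                                texture_amp = 0.05) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 4L)) stop("shape must be two integers >= 4")
  if (length(delta_range) != 2L || delta_range[1] < 0 || diff(delta_range) <= 0) {
    stop("delta_range must be (lo, hi) with lo >= 0 and hi > lo")
  }
  n_inclusions <- as.integer(n_inclusions)
  if (n_inclusions < 0L) stop("n_inclusions must be >= 0")
  lo <- delta_range[1]
  hi <- delta_range[2]
  nr <- shape[1]
  nc <- shape[2]
  # normalized coordinates in [-1, 1], row 1 at the top
  u <- outer(rep(1, nr), (seq_len(nc) - (nc + 1) / 2) / (nc / 2))
  v <- outer(((nr + 1) / 2 - seq_len(nr)) / (nr / 2), rep(1, nc))

  with_seed(seed, {
    mask <- (u / 0.88)^2 + (v / 0.80)^2 <= 1
    background <- lo + 0.65 * (hi - lo)
    delta <- matrix(lo, nr, nc)
    delta[mask] <- background

    # smooth low-frequency texture from a few broad Gaussian bumps
    if (texture_amp > 0) {
      tex <- matrix(0, nr, nc)
      for (b in seq_len(4)) {
        cx <- stats::runif(1, -0.5, 0.5)
        cy <- stats::runif(1, -0.5, 0.5)
        sg <- stats::runif(1, 0.25, 0.5)
        amp <- stats::runif(1, -1, 1)
        tex <- tex + amp * exp(-((u - cx)^2 + (v - cy)^2) / (2 * sg^2))
      }
      tex <- tex / max(abs(tex), 1e-12) * texture_amp * (hi - lo)
      delta[mask] <- delta[mask] + tex[mask]
    }

    # non-overlapping elliptical inclusions with contrasting delta
    placed <- list()
    tries <- 0L
    while (length(placed) < n_inclusions && tries < 500L) {
      tries <- tries + 1L
      cx <- stats::runif(1, -0.55, 0.55)
      cy <- stats::runif(1, -0.5, 0.5)
      a <- stats::runif(1, 0.07, 0.2)
      b <- stats::runif(1, 0.07, 0.2)
      th <- stats::runif(1, 0, pi)
      r_bound <- max(a, b)
      ok <- (cx / 0.88)^2 + (cy / 0.8)^2 <= (1 - 1.4 * r_bound)^2
      if (ok && length(placed)) {
        for (p in placed) {
          if ((cx - p$cx)^2 + (cy - p$cy)^2 < (r_bound + p$r + 0.03)^2) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      dark <- length(placed) %% 2L == 0L
      val <- if (dark) {
        stats::runif(1, lo + 0.05 * (hi - lo), lo + 0.35 * (hi - lo))
      } else {
        stats::runif(1, lo + 0.85 * (hi - lo), hi)
      }
      placed[[length(placed) + 1L]] <- list(cx = cx, cy = cy, r = r_bound, val = val)
      ur <- (u - cx) * cos(th) + (v - cy) * sin(th)
      vr <- -(u - cx) * sin(th) + (v - cy) * cos(th)
      inside <- (ur / a)^2 + (vr / b)^2 <= 1
      delta[inside & mask] <- val
    }
    if (length(placed) < n_inclusions) {
      stop("could not place ", n_inclusions, " non-overlapping inclusions; reduce the count")
    }

    delta <- pmin(pmax(delta, lo), hi)
    mu <- mu_coeff * (delta / hi)
    structure(
      list(
        delta = delta, mu = mu, mask = mask,
        delta_range = delta_range, seed = seed, n_inclusions = n_inclusions
      ),
      class = "phantom_image"
    )
  })
}

#' Analytic disk phantom
#'
#' A binary disk of radius `radius` (mm) centered at the isocenter, scaled by
#' `delta_value`. Used by analytic and oracle tests.
#'
#' @param shape Integer vector `(rows, cols)`.
#' @param radius Disk radius in mm; must be positive and fit in the field of
#'   view.
#' @param delta_value Value of delta inside the disk.
#' @param pixel_size Pixel pitch in mm.
#' @param mu_coeff Slope of the affine delta -> mu map.
#' @param antialias If `TRUE`, boundary pixels carry their area coverage
#'   fraction instead of a binary value. The default is the binary disk;
#'   the anti-aliased variant removes the O(pixel) staircase boundary
#'   roughness whose transverse derivative would otherwise not vanish under
#'   grid refinement, and is what the analytic projection oracles use.
#' @return A `phantom_image`.
#' @export
make_disk_phantom <- function(shape, radius, delta_value, pixel_size = 0.1,
                              mu_coeff = 0.02, antialias = FALSE) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 2L)) stop("shape must be two integers >= 2")
  if (radius <= 0) stop("radius must be > 0")
  fov <- min(shape) / 2 * pixel_size
  if (radius > fov) stop("radius does not fit in the field of view")
  nr <- shape[1]
  nc <- shape[2]
  x <- (seq_len(nc) - (nc + 1) / 2) * pixel_size
  y <- ((nr + 1) / 2 - seq_len(nr)) * pixel_size
  r2 <- outer(y^2, x^2, `+`)
  mask <- r2 <= radius^2
  if (antialias) {
    ss <- 8L
    off <- (seq_len(ss) - (ss + 1) / 2) / ss * pixel_size
    cov <- matrix(0, nr, nc)
    for (oy in off) {
      for (ox in off) {
        cov <- cov + (outer((y + oy)^2, (x + ox)^2, `+`) <= radius^2)
      }
    }
    delta <- delta_value * cov / ss^2
  } else {
    delta <- matrix(0, nr, nc)
    delta[mask] <- delta_value
  }
  mx <- max(abs(delta_value), 1e-12)
  structure(
    list(
      delta = delta, mu = mu_coeff * (delta / mx), mask = mask,
      delta_range = range(c(0, delta_value)), seed = NA_integer_,
      n_inclusions = 0L
    ),
    class = "phantom_image"
  )
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf(
    "<phantom_image> %d x %d, delta in [%g, %g], %d inclusion(s)\n",
    nrow(x$delta), ncol(x$delta), min(x$delta), max(x$delta), x$n_inclusions
  ))
  invisible(x)
}

#' Display a phantom, image or sinogram as a grayscale raster
#'
#' @param x A matrix, `phantom_image` or `dpc_sinogram`.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot_image <- function(x, main = NULL, ...) {
  m <- if (inherits(x, "dpc_sinogram")) x$phi else as_image_matrix(x)
  # orient so row 1 is drawn at the top
  graphics::image(
    t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
    col = grDevices::gray.colors(256, 0, 1),
    axes = FALSE, asp = nrow(m) / ncol(m), main = main, ...
  )
  invisible(x)
}
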