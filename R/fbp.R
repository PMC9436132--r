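#' Filtered backprojection with the Hilbert filter
#'
#' Analytic (pseudo-inverse) DPC reconstruction. Because the DPC signal is
#' the transverse derivative of the projection, the ramp filter of ordinary
#' FBP factors into the derivative already present in the data and the
#' imaginary-sign (Hilbert) filter `-i * sign(nu) / (2 * pi * sensitivity)`,
#' which is applied along the detector coordinate in the frequency domain
#' before backprojecting. An optional Hann window tapers the filter at high
#' frequency.
#'
#' @param phi A `dpc_sinogram` (parallel geometry; rebin fan data first).
#' @param geometry Optional [scan_geometry()] override (defaults to the
#'   sinogram's).
#' @param sensitivity Interferometer spec or scalar sensitivity used to
#'   undo the fringe-phase scaling.
#' @param window `"none"` or `"hann"`.
#' @param pad_factor Zero-padding factor for the detector-axis FFT.
#' @return Reconstructed image matrix (approximates delta).
#' @export
fbp_hilbert <- function(phi, geometry = NULL, sensitivity = 1,
                        window = c("none", "hann"), pad_factor = 4) {
  window <- match.arg(window)
  m <- if (inherits(phi, "dpc_sinogram")) phi$phi else phi
  geometry <- geometry %||% (if (inherits(phi, "dpc_sinogram")) phi$geometry else NULL)
  if (is.null(geometry)) stop("geometry is required when phi is a bare matrix")
  if (geometry$mode != "parallel") {
    stop("fbp_hilbert expects parallel geometry; rebin fan data first")
  }
  if (geometry$n_angles < 8) {
    warning("very few projection angles; FBP quality will be poor")
  }
  sens <- gi_sensitivity(sensitivity)
  n_det <- geometry$n_det
  n_pad <- 2^ceiling(log2(max(8, pad_factor * n_det)))
  # frequency sign vector of the padded axis
  kidx <- seq_len(n_pad) - 1L
  nu_sign <- ifelse(kidx == 0, 0, ifelse(kidx < n_pad / 2, 1, ifelse(kidx == n_pad / 2, 0, -1)))
  filt <- -1i * nu_sign / (2 * pi * sens)
  if (window == "hann") {
    nu_frac <- pmin(kidx, n_pad - kidx) / (n_pad / 2)
    filt <- filt * (0.5 + 0.5 * cos(pi * nu_frac))
  }
  # filter all rows; center the detector data in the padded window to keep
  # circular wrap-around far from the support
  off <- floor((n_pad - n_det) / 2)
  filtered <- matrix(0, geometry$n_angles, n_det)
  for (a in seq_len(geometry$n_angles)) {
    row <- numeric(n_pad)
    row[off + seq_len(n_det)] <- m[a, ]
    q <- Re(stats::fft(stats::fft(row) * filt, inverse = TRUE)) / n_pad
    filtered[a, ] <- q[off + seq_len(n_det)]
  }
  # backproject with linear interpolation along the detector coordinate
  s_det <- detector_coords(geometry)
  pc <- pixel_coords(geometry)
  dp <- geometry$det_pitch
  img <- numeric(prod(geometry$image_shape))
  for (a in seq_len(geometry$n_angles)) {
    th <- geometry$angles[a]
    s <- pc$x * cos(th) + pc$y * sin(th)
    t <- (s - s_det[1]) / dp
    i0 <- pmin(pmax(floor(t), 0), n_det - 2)
    frac <- pmin(pmax(t - i0, 0), 1)
    vals <- filtered[a, i0 + 1] * (1 - frac) + filtered[a, i0 + 2] * frac
    vals[t < 0 | t > n_det - 1] <- 0
    img <- img + vals
  }
  img <- img * (pi / geometry$n_angles)
  matrix(img, nrow = geometry$image_shape[1])
}

#' FBP followed by learned post-processing
#'
#' The deep-learning comparator: a Hilbert-filter FBP whose output is passed
#' once through the (same) trained denoiser.
#'
#' @inheritParams fbp_hilbert
#' @param denoiser As in [pnp_lbfgs()].
#' @return Image matrix.
#' @export
postprocess_fbp <- function(phi, geometry = NULL, denoiser = NULL,
                            sensitivity = 1, window = c("none", "hann")) {
  fdn <- as_denoiser_fun(denoiser)
  fdn(fbp_hilbert(phi, geometry, sensitivity = sensitivity, window = window))
}
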