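#' Describe a 2D DPC-CT acquisition geometry
#'
#' A `scan_geometry` fixes everything the projectors need: beam shape
#' (parallel or fan), rotation angles, detector sampling and the image grid.
#' Pixel centers live on a Cartesian grid centered at the isocenter; index
#' `[1, 1]` is the top-left pixel, `x` increases with the column index and is
#' the differentiation direction of the interferometer (perpendicular to the
#' grating lines), `y` increases upwards.
#'
#' @param mode `"parallel"` or `"fan"`.
#' @param n_angles Number of projection angles.
#' @param n_det Number of detector columns.
#' @param det_pitch Detector element width (mm).
#' @param pixel_size Image pixel pitch (mm).
#' @param image_shape Integer vector `(rows, cols)` of the reconstruction grid.
#' @param angles Optional strictly increasing rotation angles in radians.
#'   Defaults to a uniform sampling of `[0, pi)` (parallel) or `[0, 2*pi)` (fan).
#' @param src_iso Source-to-isocenter distance (mm, fan mode only).
#' @param iso_det Isocenter-to-detector distance (mm, fan mode only).
#'
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(mode = c("parallel", "fan"),
                          n_angles,
                          n_det,
                          det_pitch,
                          pixel_size,
                          image_shape,
                          angles = NULL,
                          src_iso = NULL,
                          iso_det = NULL) {
  mode <- match.arg(mode)
  n_angles <- as.integer(n_angles)
  n_det <- as.integer(n_det)
  if (n_angles < 1L) stop("n_angles must be >= 1")
  if (n_det < 1L) stop("n_det must be >= 1")
  if (det_pitch <= 0) stop("det_pitch must be > 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 1L)) {
    stop("image_shape must be two positive integers (rows, cols)")
  }
  if (is.null(angles)) {
    span <- if (mode == "parallel") pi else 2 * pi
    angles <- seq(0, span, length.out = n_angles + 1L)[seq_len(n_angles)]
  }
  if (length(angles) != n_angles) stop("length(angles) must equal n_angles")
  if (n_angles > 1L && any(diff(angles) <= 0)) stop("angles must be strictly increasing")
  if (mode == "fan") {
    if (is.null(src_iso) || src_iso <= 0) stop("fan mode requires src_iso > 0")
    if (is.null(iso_det) || iso_det < 0) stop("fan mode requires iso_det >= 0")
  } else {
    src_iso <- NULL
    iso_det <- NULL
  }
  structure(
    list(
      mode = mode, n_angles = n_angles, angles = as.numeric(angles),
      n_det = n_det, det_pitch = det_pitch,
      src_iso = src_iso, iso_det = iso_det,
      pixel_size = pixel_size, image_shape = image_shape
    ),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> %s beam, %d angles, %d detector columns (pitch %g mm)\n",
    x$mode, x$n_angles, x$n_det, x$det_pitch
  ))
  cat(sprintf(
    "  image %d x %d pixels (%g mm)\n",
    x$image_shape[1], x$image_shape[2], x$pixel_size
  ))
  if (x$mode == "fan") {
    cat(sprintf("  src-iso %g mm, iso-det %g mm\n", x$src_iso, x$iso_det))
  }
  invisible(x)
}

# Pixel-center coordinates (mm) in column-major vector order, matching
# as.vector() of an image matrix. Row 1 is the top of the image.
pixel_coords <- function(geometry) {
  nr <- geometry$image_shape[1]
  nc <- geometry$image_shape[2]
  ps <- geometry$pixel_size
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  list(
    x = (col - (nc + 1) / 2) * ps,
    y = ((nr + 1) / 2 - row) * ps
  )
}

# Detector-column center coordinates (mm) along the detector line.
detector_coords <- function(geometry) {
  (seq_len(geometry$n_det) - (geometry$n_det + 1) / 2) * geometry$det_pitch
}

#' Describe the Talbot-Lau interferometer
#'
#' Holds the design X-ray wavelength, the origin-to-analyzer-grating distance
#' `d2` and the analyzer grating pitch `g2`. The phase sensitivity of the
#' interferometer -- the fringe phase produced per unit refraction angle --
#' follows from the fringe shift `d2 * alpha` expressed as a fraction of the
#' grating pitch: `sensitivity = 2 * pi * d2 / g2`.
#'
#' @param wavelength Design X-ray wavelength (m).
#' @param d2 Origin-to-G2 distance (m).
#' @param g2 Pitch of the G2 analyzer grating (m).
#' @return An object of class `interferometer_spec`.
#' @export
interferometer_spec <- function(wavelength = 4.6e-11, d2 = 0.25, g2 = 4.2e-6) {
  if (wavelength <= 0 || d2 <= 0 || g2 <= 0) {
    stop("wavelength, d2 and g2 must all be strictly positive")
  }
  s <- 2 * pi * d2 / g2
  if (!is.finite(s)) stop("sensitivity is not finite")
  structure(
    list(wavelength = wavelength, d2 = d2, g2 = g2),
    class = "interferometer_spec"
  )
}

#' Fringe-phase sensitivity of an interferometer
#'
#' Returns the conversion factor from refraction angle to fringe phase,
#' `2 * pi * d2 / g2` (radians per radian of refraction).
#'
#' @param spec An [interferometer_spec()], or a bare positive number that is
#'   returned unchanged (convenient for unit-rescaled phantom work where the
#'   sensitivity is set directly).
#' @return A scalar sensitivity.
#' @export
gi_sensitivity <- function(spec) {
  if (is.numeric(spec) && length(spec) == 1L) {
    if (spec <= 0) stop("sensitivity must be > 0")
    return(as.numeric(spec))
  }
  if (!inherits(spec, "interferometer_spec")) {
    stop("spec must be an interferometer_spec or a positive scalar")
  }
  2 * pi * spec$d2 / spec$g2
}
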