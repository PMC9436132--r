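# On-disk exchange: float TIFF images with JSON sidecars.
#
# The TIFF writer available here stores samples in [0, 1], so images are
# affinely normalized on write and the (offset, scale) pair recorded in the
# sidecar restores the original values losslessly to float precision.

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image (or sinogram) as float TIFF with a JSON sidecar
#'
#' @param img Image matrix.
#' @param path Output TIFF path.
#' @param metadata Named list stored in the JSON sidecar alongside the
#'   normalization constants (geometry, seeds, ...).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path, metadata = list()) {
  stopifnot(is.matrix(img))
  lo <- min(img)
  hi <- max(img)
  scale <- if (hi > lo) hi - lo else 1
  norm <- (img - lo) / scale
  suppressWarnings(tiff::writeTIFF(norm, path, bits.per.sample = 32L, reduce = FALSE))
  meta <- c(metadata, list(
    offset = lo, scale = scale, dim = dim(img), format = "float32-normalized"
  ))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image written by [write_image_tiff()]
#'
#' @param path TIFF path (sidecar expected beside it).
#' @return `list(image, metadata)`.
#' @export
read_image_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  norm <- tiff::readTIFF(path)
  img <- norm * meta$scale + meta$offset
  list(image = img, metadata = meta)
}

#' Write a phase-stepping stack as a multi-page TIFF with a JSON sidecar
#'
#' One page per phase step; step phases, geometry and normalization live in
#' the sidecar.
#'
#' @param stack A `phase_stepping_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "phase_stepping_stack"))
  cmax <- max(stack$counts, 1)
  pages <- lapply(seq_len(dim(stack$counts)[1]), function(j) {
    stack$counts[j, , ] / cmax
  })
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE))
  g <- stack$geometry
  meta <- list(
    scale = cmax, step_phases = stack$step_phases,
    n_angles = g$n_angles, n_det = g$n_det, det_pitch = g$det_pitch,
    pixel_size = g$pixel_size, image_shape = g$image_shape, mode = g$mode,
    src_iso = g$src_iso, iso_det = g$iso_det, angles = g$angles
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phase-stepping stack written by [write_stack_tiff()]
#'
#' @param path TIFF path.
#' @return A `phase_stepping_stack`.
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  counts <- array(0, c(length(pages), dim(pages[[1]])))
  for (j in seq_along(pages)) counts[j, , ] <- pages[[j]] * meta$scale
  geometry <- scan_geometry(
    mode = meta$mode, n_angles = meta$n_angles, n_det = meta$n_det,
    det_pitch = meta$det_pitch, pixel_size = meta$pixel_size,
    image_shape = meta$image_shape, angles = meta$angles,
    src_iso = meta$src_iso, iso_det = meta$iso_det
  )
  structure(
    list(counts = counts, step_phases = meta$step_phases, geometry = geometry),
    class = "phase_stepping_stack"
  )
}

#' Save a trained denoiser as JSON
#'
#' Kernels, architecture, certified spectral state and the training
#' configuration are serialized to a single (plain-text) JSON file at full
#' float precision.
#'
#' @param denoiser A `trained_denoiser` (or bare `bias_free_net`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_denoiser <- function(denoiser, path) {
  net <- if (inherits(denoiser, "trained_denoiser")) denoiser$net else denoiser
  obj <- list(
    widths = net$widths, kernel_size = net$kernel_size,
    input_shape = net$input_shape,
    kernels = lapply(net$layers, function(l) {
      list(dim = dim(l$kernel), values = as.vector(l$kernel))
    })
  )
  if (inherits(denoiser, "trained_denoiser")) {
    obj$spectral_norms <- denoiser$spectral_state$norms
    obj$spectral_product <- denoiser$spectral_state$product
    obj$config <- denoiser$config[c(
      "lambda_reg", "epsilon", "epochs", "batch_size", "lr", "seed"
    )]
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a denoiser written by [write_denoiser()]
#'
#' @param path JSON path.
#' @return A `bias_free_net` (with certified norms attached as attributes
#'   when present in the file).
#' @export
read_denoiser <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(seq_len(nrow_or_len(obj$kernels)), function(l) {
    k <- if (is.data.frame(obj$kernels)) obj$kernels[l, ] else obj$kernels[[l]]
    list(kernel = array(unlist(k$values), unlist(k$dim)))
  })
  net <- structure(
    list(
      layers = layers, widths = obj$widths,
      kernel_size = obj$kernel_size, input_shape = obj$input_shape
    ),
    class = "bias_free_net"
  )
  if (!is.null(obj$spectral_product)) {
    attr(net, "spectral_norms") <- obj$spectral_norms
    attr(net, "spectral_product") <- obj$spectral_product
  }
  net
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
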