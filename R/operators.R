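#' Kaiser-Bessel DPC forward/backward operator pair
#'
#' Builds the linear differential phase-contrast projector for a geometry.
#' The image is parameterized by Kaiser-Bessel blobs whose analytic
#' derivative is tabulated once ([build_lookup()]); the ray-driven forward
#' operator then accumulates, for every ray (one per detector-element
#' center), the tabulated derivative evaluated at the signed perpendicular
#' distance between the ray and each blob center within the support
#' half-width `w`. Both the forward map and the voxel-driven backward map
#' are materialized as sparse matrices, so linearity is structural and the
#' `matched` adjoint is the literal transpose.
#'
#' The physical prefactor maps the transverse derivative of the line
#' integral of delta to fringe phase: `sensitivity * pixel_size^2 / area(w_kb)`,
#' where the grid-spacing weight `pixel_size^2 / area(w_kb)` makes the
#' unweighted lattice sum of blob derivatives a consistent discretization of
#' `sensitivity * d/ds integral(delta dl)` under grid refinement.
#'
#' @param geometry A [scan_geometry()].
#' @param sensitivity Fringe-phase sensitivity: an [interferometer_spec()] or
#'   a bare positive scalar (see [gi_sensitivity()]).
#' @param kb Optional [build_lookup()] profile; default uses `alpha_kb = 3`
#'   and `w` twice the pixel pitch.
#' @param adjoint_mode `"matched"` (exact transpose of the forward map; the
#'   default, preserving the convex-quadratic structure of the data term) or
#'   `"voxel_driven"` (the independently constructed voxel-driven
#'   backprojector; identical to matched in parallel geometry).
#' @return A `dpc_operator_pair`.
#' @export
dpc_operator <- function(geometry,
                         sensitivity = 1,
                         kb = NULL,
                         adjoint_mode = c("matched", "voxel_driven")) {
  stopifnot(inherits(geometry, "scan_geometry"))
  adjoint_mode <- match.arg(adjoint_mode)
  sens <- gi_sensitivity(sensitivity)
  if (is.null(kb)) {
    kb <- build_lookup(alpha_kb = 3, w = 2 * geometry$pixel_size)
  }
  scale <- sens * geometry$pixel_size^2 / kb$area
  A <- build_kb_forward_matrix(geometry, kb, scale)
  structure(
    list(
      geometry = geometry, kb = kb, kind = "kb",
      sensitivity = sens, scale = scale,
      adjoint_mode = adjoint_mode, A = A,
      cache = new.env(parent = emptyenv())
    ),
    class = "dpc_operator_pair"
  )
}

#' Finite-difference DPC operator pair (baseline)
#'
#' The classical construction: an interpolating ray-sum (Radon) projector
#' followed by central differencing across detector columns, divided by the
#' detector pitch and scaled by the interferometer sensitivity. The backward
#' operator is the exact transpose.
#'
#' @inheritParams dpc_operator
#' @return A `dpc_operator_pair` with `kind = "fd"`.
#' @export
fd_operator <- function(geometry, sensitivity = 1) {
  stopifnot(inherits(geometry, "scan_geometry"))
  sens <- gi_sensitivity(sensitivity)
  R <- build_raysum_matrix(geometry)
  D <- build_diff_matrix(geometry)
  A <- sens * (D %*% R)
  structure(
    list(
      geometry = geometry, kb = NULL, kind = "fd",
      sensitivity = sens, scale = sens,
      adjoint_mode = "matched", A = A, raysum = R,
      cache = new.env(parent = emptyenv())
    ),
    class = "dpc_operator_pair"
  )
}

#' @export
print.dpc_operator_pair <- function(x, ...) {
  cat(sprintf(
    "<dpc_operator_pair> %s operator, %d rays x %d voxels, adjoint '%s'\n",
    x$kind, nrow(x$A), ncol(x$A), x$adjoint_mode
  ))
  invisible(x)
}

# Per-angle ray bundle in the frame rotated with the gantry.
# Returns for every voxel its detector-plane abscissa q (mm), the local
# magnification M (1 for parallel beam) and the rotated coordinates.
project_voxels <- function(geometry, theta) {
  pc <- pixel_coords(geometry)
  ct <- cos(theta)
  st <- sin(theta)
  xr <- pc$x * ct + pc$y * st
  if (geometry$mode == "parallel") {
    list(q = xr, M = rep(1, length(xr)), xr = xr, yr = NULL)
  } else {
    yr <- -pc$x * st + pc$y * ct
    R1 <- geometry$src_iso
    R2 <- geometry$iso_det
    M <- (R1 + R2) / (R1 - yr)
    list(q = xr * M, M = M, xr = xr, yr = yr)
  }
}

# Ray-driven forward matrix: rows are rays (angle-major, detector within),
# columns voxels; entries scale * dw(signed perpendicular distance).
build_kb_forward_matrix <- function(geometry, kb, scale) {
  n_det <- geometry$n_det
  dp <- geometry$det_pitch
  s_det <- detector_coords(geometry)
  n_pix <- prod(geometry$image_shape)
  w <- kb$w
  ii <- list()
  jj <- list()
  vv <- list()
  idx <- 1L
  for (a in seq_len(geometry$n_angles)) {
    th <- geometry$angles[a]
    pv <- project_voxels(geometry, th)
    K <- if (geometry$mode == "parallel") {
      ceiling(w / dp) + 1L
    } else {
      ceiling(w * max(pv$M) / dp) + 1L
    }
    m_near <- round((pv$q - s_det[1]) / dp) + 1
    vox <- seq_len(n_pix)
    for (j in (-K):K) {
      m <- m_near + j
      ok <- m >= 1 & m <= n_det
      if (!any(ok)) next
      mo <- m[ok]
      if (geometry$mode == "parallel") {
        d <- s_det[mo] - pv$xr[ok]
      } else {
        d <- fan_perp_distance(geometry, th, pv$xr[ok], pv$yr[ok], s_det[mo])
      }
      keep <- abs(d) <= w
      if (!any(keep)) next
      val <- scale * kb_lookup(kb, d[keep], derivative = TRUE)
      nz <- val != 0
      if (!any(nz)) next
      ii[[idx]] <- (a - 1L) * n_det + mo[keep][nz]
      jj[[idx]] <- vox[ok][keep][nz]
      vv[[idx]] <- val[nz]
      idx <- idx + 1L
    }
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(vv),
    dims = c(geometry$n_angles * n_det, n_pix)
  )
}

# Signed perpendicular distance between fan rays and voxel centers, in the
# rotated frame: source at (0, R1), detector line y = -R2, element at s_m.
# Positive when the ray passes on the +x side of the voxel, matching the
# parallel-beam convention d = s_det - s_voxel.
fan_perp_distance <- function(geometry, theta, xr, yr, s_m) {
  R1 <- geometry$src_iso
  R2 <- geometry$iso_det
  vx <- s_m
  vy <- -(R1 + R2)
  vn <- sqrt(vx^2 + vy^2)
  # unit normal with positive x-component: n = (-vy, vx) / |v|
  nx <- -vy / vn
  ny <- vx / vn
  # (S - p) . n with S = (0, R1)
  (0 - xr) * nx + (R1 - yr) * ny
}

# Voxel-driven backprojection matrix (n_pix x n_rays): project each voxel
# center along its source ray to the detector plane and sample the
# derivative lookup at the detector-plane distances, magnification-scaled
# in fan mode.
build_kb_backward_matrix <- function(geometry, kb, scale) {
  n_det <- geometry$n_det
  dp <- geometry$det_pitch
  s_det <- detector_coords(geometry)
  n_pix <- prod(geometry$image_shape)
  w <- kb$w
  ii <- list()
  jj <- list()
  vv <- list()
  idx <- 1L
  for (a in seq_len(geometry$n_angles)) {
    th <- geometry$angles[a]
    pv <- project_voxels(geometry, th)
    K <- ceiling(w * max(pv$M) / dp) + 1L
    m_near <- round((pv$q - s_det[1]) / dp) + 1
    vox <- seq_len(n_pix)
    for (j in (-K):K) {
      m <- m_near + j
      ok <- m >= 1 & m <= n_det
      if (!any(ok)) next
      mo <- m[ok]
      t_det <- s_det[mo] - pv$q[ok]
      M <- pv$M[ok]
      d <- t_det / M
      keep <- abs(d) <= w
      if (!any(keep)) next
      val <- scale * kb_lookup(kb, d[keep], derivative = TRUE)
      nz <- val != 0
      if (!any(nz)) next
      jj[[idx]] <- (a - 1L) * n_det + mo[keep][nz]
      ii[[idx]] <- vox[ok][keep][nz]
      vv[[idx]] <- val[nz]
      idx <- idx + 1L
    }
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(vv),
    dims = c(n_pix, geometry$n_angles * n_det)
  )
}

# Interpolating ray-sum (Radon) matrix with a triangle kernel of half-width
# one detector pitch; the weight ps^2 / dp makes the lattice sum a
# consistent line-integral quadrature.
build_raysum_matrix <- function(geometry) {
  n_det <- geometry$n_det
  dp <- geometry$det_pitch
  s_det <- detector_coords(geometry)
  n_pix <- prod(geometry$image_shape)
  wgt <- geometry$pixel_size^2 / dp
  ii <- list()
  jj <- list()
  vv <- list()
  idx <- 1L
  for (a in seq_len(geometry$n_angles)) {
    th <- geometry$angles[a]
    pv <- project_voxels(geometry, th)
    m_near <- round((pv$q - s_det[1]) / dp) + 1
    vox <- seq_len(n_pix)
    for (j in -1:1) {
      m <- m_near + j
      ok <- m >= 1 & m <= n_det
      if (!any(ok)) next
      mo <- m[ok]
      d <- abs(s_det[mo] - pv$q[ok]) / dp
      keep <- d < 1
      if (!any(keep)) next
      val <- wgt * (1 - d[keep])
      ii[[idx]] <- (a - 1L) * n_det + mo[keep]
      jj[[idx]] <- vox[ok][keep]
      vv[[idx]] <- val
      idx <- idx + 1L
    }
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(vv),
    dims = c(geometry$n_angles * n_det, n_pix)
  )
}

# Block-diagonal differencing across detector columns: central differences
# in the interior, one-sided at the detector edges, divided by det_pitch.
build_diff_matrix <- function(geometry) {
  n_det <- geometry$n_det
  dp <- geometry$det_pitch
  i <- integer(0)
  j <- integer(0)
  x <- numeric(0)
  for (a in seq_len(geometry$n_angles)) {
    off <- (a - 1L) * n_det
    m <- 2:(n_det - 1L)
    i <- c(i, off + m, off + m, off + 1L, off + 1L, off + n_det, off + n_det)
    j <- c(j, off + m + 1L, off + m - 1L, off + 2L, off + 1L, off + n_det, off + n_det - 1L)
    x <- c(
      x, rep(1 / (2 * dp), n_det - 2L), rep(-1 / (2 * dp), n_det - 2L),
      1 / dp, -1 / dp, 1 / dp, -1 / dp
    )
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = rep(geometry$n_angles * n_det, 2))
}

#' Apply the DPC forward operator
#'
#' Rays are independent: the output for any subset of rays equals the
#' corresponding subset of the full sinogram.
#'
#' @param delta A `phantom_image` or an image matrix matching the geometry.
#' @param op A [dpc_operator()] or [fd_operator()] pair.
#' @return A `dpc_sinogram` (`n_angles x n_det` matrix of fringe phases, in
#'   radians, unwrapped).
#' @export
forward_project <- function(delta, op) {
  stopifnot(inherits(op, "dpc_operator_pair"))
  img <- as_image_matrix(delta)
  if (!all(dim(img) == op$geometry$image_shape)) {
    stop("image shape does not match the operator geometry")
  }
  stop_if_not_finite(img, "delta")
  y <- as.numeric(op$A %*% as.vector(img))
  phi <- matrix(y, nrow = op$geometry$n_angles, ncol = op$geometry$n_det, byrow = TRUE)
  dpc_sinogram(phi, op$geometry)
}

#' Apply the DPC backward operator
#'
#' `matched` mode scatters exactly the forward weights (literal transpose);
#' `voxel_driven` mode uses the independently built voxel-driven matrix. In
#' parallel geometry the two coincide.
#'
#' @param phi A `dpc_sinogram` or `n_angles x n_det` matrix.
#' @param op A `dpc_operator_pair`.
#' @param mode Override the pair's `adjoint_mode`.
#' @return An image matrix.
#' @export
back_project <- function(phi, op, mode = NULL) {
  stopifnot(inherits(op, "dpc_operator_pair"))
  mode <- mode %||% op$adjoint_mode
  m <- if (inherits(phi, "dpc_sinogram")) phi$phi else phi
  if (!all(dim(m) == c(op$geometry$n_angles, op$geometry$n_det))) {
    stop("sinogram shape does not match the operator geometry")
  }
  y <- as.vector(t(m)) # ray order: angle-major, detector within
  v <- if (mode == "voxel_driven") {
    if (op$kind != "kb") stop("voxel_driven mode applies to the Kaiser-Bessel pair")
    B <- voxel_driven_matrix(op)
    as.numeric(B %*% y)
  } else {
    as.numeric(Matrix::crossprod(op$A, y))
  }
  matrix(v, nrow = op$geometry$image_shape[1], ncol = op$geometry$image_shape[2])
}

voxel_driven_matrix <- function(op) {
  if (is.null(op$cache$Bvd)) {
    op$cache$Bvd <- build_kb_backward_matrix(op$geometry, op$kb, op$scale)
  }
  op$cache$Bvd
}

#' @rdname forward_project
#' @export
fd_forward <- function(delta, op) {
  if (op$kind != "fd") stop("fd_forward expects an fd_operator pair")
  forward_project(delta, op)
}

#' @rdname back_project
#' @export
fd_backward <- function(phi, op) {
  if (op$kind != "fd") stop("fd_backward expects an fd_operator pair")
  back_project(phi, op, mode = "matched")
}

#' Construct a DPC sinogram container
#'
#' @param phi `n_angles x n_det` matrix of differential-phase values
#'   (radians).
#' @param geometry The generating [scan_geometry()].
#' @param mask Optional logical matrix flagging unusable (dead-pixel)
#'   entries.
#' @return A `dpc_sinogram`.
#' @export
dpc_sinogram <- function(phi, geometry, mask = NULL) {
  stopifnot(is.matrix(phi), inherits(geometry, "scan_geometry"))
  if (!all(dim(phi) == c(geometry$n_angles, geometry$n_det))) {
    stop("phi must be n_angles x n_det")
  }
  structure(
    list(phi = phi, geometry = geometry, mask = mask),
    class = "dpc_sinogram"
  )
}

#' @export
print.dpc_sinogram <- function(x, ...) {
  cat(sprintf(
    "<dpc_sinogram> %d angles x %d detector columns, phi in [%.3g, %.3g] rad\n",
    nrow(x$phi), ncol(x$phi), min(x$phi), max(x$phi)
  ))
  invisible(x)
}

#' Normalized singular-value spectrum of the normal matrix
#'
#' Materializes the forward map as a dense matrix and returns the
#' eigenvalues of `A' A` (the squared singular values of `A`) sorted in
#' decreasing order and normalized to a maximum of 1. The decay rate of this
#' spectrum quantifies the ill-conditioning of the DPC inverse problem; a
#' slower decay means better-conditioned data updates.
#'
#' @param op A `dpc_operator_pair`.
#' @param max_side Guard: refuse images larger than `max_side^2` unknowns
#'   (dense decomposition; use an iterative top-k method beyond that).
#' @return Numeric vector of normalized spectrum values.
#' @export
normal_matrix_spectrum <- function(op, max_side = 64) {
  stopifnot(inherits(op, "dpc_operator_pair"))
  n_pix <- prod(op$geometry$image_shape)
  if (n_pix > max_side^2) {
    stop(
      "image has ", n_pix, " unknowns; the dense spectrum is capped at ",
      max_side^2, ". Use an iterative top-k (power/Lanczos) variant for larger sizes."
    )
  }
  d <- svd(as.matrix(op$A), nu = 0, nv = 0)$d
  ev <- sort(d^2, decreasing = TRUE)
  ev / ev[1]
}
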