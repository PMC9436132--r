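#' Wrap a phase to the principal branch
#'
#' Maps any finite phase to the congruent value (mod 2*pi) in `(-pi, pi]`.
#' Phase-stepping retrieval can only observe this principal value, which is
#' what produces wrapping artifacts at strong edges.
#'
#' @param x Phases in radians.
#' @return Wrapped phases in `(-pi, pi]`.
#' @export
wrap_phase <- function(x) {
  stop_if_not_finite(x, "phase")
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Flat-field maps of a Talbot-Lau interferometer
#'
#' Per-detector-element mean flat intensity `I0` (counts), fringe visibility
#' `V0` (in `(0, 1]`) and reference fringe phase `Phi0` (radians). Scalars
#' are expanded over the sinogram; `Phi0` can optionally be a smooth random
#' field for realism.
#'
#' @param geometry A [scan_geometry()].
#' @param I0 Mean flat counts per element.
#' @param V0 Flat-field visibility; low values emulate the high-noise regime
#'   of low-visibility interferometers.
#' @param Phi0 Reference phase; scalar, matrix, or `"random"` for a smooth
#'   random field.
#' @param seed Seed used when `Phi0 = "random"`.
#' @return A `flat_field_maps` object of `n_angles x n_det` matrices.
#' @export
flat_field_maps <- function(geometry, I0 = 120000, V0 = 0.3, Phi0 = 0, seed = 1) {
  stopifnot(inherits(geometry, "scan_geometry"))
  dm <- c(geometry$n_angles, geometry$n_det)
  expand <- function(v) {
    if (is.matrix(v)) {
      stopifnot(all(dim(v) == dm))
      v
    } else {
      matrix(v, dm[1], dm[2])
    }
  }
  if (identical(Phi0, "random")) {
    Phi0 <- with_seed(seed, {
      s <- detector_coords(geometry)
      base <- 0.5 * sin(2 * pi * s / (geometry$n_det * geometry$det_pitch) * stats::runif(1, 1, 3) +
        stats::runif(1, 0, 2 * pi))
      matrix(base, dm[1], dm[2], byrow = TRUE)
    })
  }
  I0 <- expand(I0)
  V0 <- expand(V0)
  Phi0 <- expand(Phi0)
  if (any(I0 <= 0)) stop("I0 must be > 0")
  if (any(V0 <= 0 | V0 > 1)) stop("V0 must lie in (0, 1]")
  if (any(Phi0 <= -pi | Phi0 > pi)) stop("Phi0 must lie in (-pi, pi]")
  structure(list(I0 = I0, V0 = V0, Phi0 = Phi0), class = "flat_field_maps")
}

#' Simulate Talbot-Lau phase stepping with Poisson noise
#'
#' Computes the three contrast channels of the phantom -- transmission from
#' the attenuation line integrals, an optional dark-field channel, and the
#' differential phase from the Kaiser-Bessel forward projector -- then
#' evaluates the phase-stepping curve
#' `I_k = I0 * T * (1 + V0 * D * cos(k + Phi0 - phi))`
#' at each grating step and draws Poisson counts with those means. A
#' sample-free flat stack is returned alongside. Step phases are uniform,
#' `k_j = 2*pi*(j-1)/n_steps`, which makes the two-harmonic Fourier
#' retrieval exact in the noiseless limit.
#'
#' @param phantom A `phantom_image`.
#' @param geometry A [scan_geometry()].
#' @param sensitivity Interferometer spec or scalar sensitivity (see
#'   [gi_sensitivity()]).
#' @param flats Optional [flat_field_maps()]; default is spatially constant
#'   `I0 = photons`, `V0 = 0.3`, `Phi0 = 0`.
#' @param n_steps Number of phase steps (>= 3; default 5).
#' @param photons Mean flat counts per element per step.
#' @param seed RNG seed; the simulation is deterministic given the seed.
#' @param dark_field Optional epsilon map (same shape as the image) whose
#'   line integrals produce `D = exp(-integral(eps dl))`; default `D = 1`.
#' @param op Optional pre-built [dpc_operator()] (saves rebuilding the
#'   projector); must match `geometry`.
#' @param noiseless If `TRUE`, the stacks contain the exact stepping-curve
#'   means instead of Poisson draws.
#' @return A list with `sample` and `flat` (`phase_stepping_stack`s), plus
#'   the noiseless ground truth `phi_true`, `T_true`, `D_true`.
#' @export
simulate_phase_stepping <- function(phantom,
                                    geometry,
                                    sensitivity = 1,
                                    flats = NULL,
                                    n_steps = 5,
                                    photons = 120000,
                                    seed = 1,
                                    dark_field = NULL,
                                    op = NULL,
                                    noiseless = FALSE) {
  stopifnot(inherits(phantom, "phantom_image"), inherits(geometry, "scan_geometry"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 3L) stop("n_steps must be >= 3")
  if (photons <= 0) stop("photons must be > 0")
  if (!all(dim(phantom$delta) == geometry$image_shape)) {
    stop("phantom shape does not match geometry$image_shape")
  }
  if (is.null(op)) {
    op <- dpc_operator(geometry, sensitivity = sensitivity)
  } else if (!isTRUE(all.equal(op$geometry$image_shape, geometry$image_shape))) {
    stop("op geometry does not match")
  }
  if (is.null(flats)) flats <- flat_field_maps(geometry, I0 = photons, V0 = 0.3, Phi0 = 0)

  phi_true <- forward_project(phantom$delta, op)$phi
  Rmat <- raysum_matrix_for(op)
  T_true <- if (is.null(phantom$mu)) {
    matrix(1, geometry$n_angles, geometry$n_det)
  } else {
    li <- as.numeric(Rmat %*% as.vector(phantom$mu))
    exp(-matrix(li, geometry$n_angles, geometry$n_det, byrow = TRUE))
  }
  D_true <- if (is.null(dark_field)) {
    matrix(1, geometry$n_angles, geometry$n_det)
  } else {
    li <- as.numeric(Rmat %*% as.vector(dark_field))
    exp(-matrix(li, geometry$n_angles, geometry$n_det, byrow = TRUE))
  }

  step_phases <- 2 * pi * (seq_len(n_steps) - 1) / n_steps
  dims <- c(n_steps, geometry$n_angles, geometry$n_det)
  mean_sample <- array(0, dims)
  mean_flat <- array(0, dims)
  for (j in seq_len(n_steps)) {
    k <- step_phases[j]
    mean_sample[j, , ] <- flats$I0 * T_true *
      (1 + flats$V0 * D_true * cos(k + flats$Phi0 - phi_true))
    mean_flat[j, , ] <- flats$I0 * (1 + flats$V0 * cos(k + flats$Phi0))
  }
  if (noiseless) {
    counts_sample <- mean_sample
    counts_flat <- mean_flat
  } else {
    draws <- with_seed(seed, {
      list(
        s = stats::rpois(length(mean_sample), lambda = as.vector(mean_sample)),
        f = stats::rpois(length(mean_flat), lambda = as.vector(mean_flat))
      )
    })
    counts_sample <- array(draws$s, dims)
    counts_flat <- array(draws$f, dims)
  }
  mk <- function(counts) {
    structure(
      list(counts = counts, step_phases = step_phases, geometry = geometry),
      class = "phase_stepping_stack"
    )
  }
  list(
    sample = mk(counts_sample), flat = mk(counts_flat),
    phi_true = phi_true, T_true = T_true, D_true = D_true
  )
}

# ray-sum matrix reuse: fd pairs carry one; kb pairs cache one
raysum_matrix_for <- function(op) {
  if (!is.null(op$raysum)) {
    return(op$raysum)
  }
  if (is.null(op$cache$raysum)) {
    op$cache$raysum <- build_raysum_matrix(op$geometry)
  }
  op$cache$raysum
}

#' Retrieve transmission, dark-field and differential phase
#'
#' Fourier analysis of the phase-stepping curves: the zeroth and first
#' discrete harmonics of sample and flat stacks give, per detector element,
#' `T = a0_sample / a0_flat`, `D = V_sample / V_flat` with `V = |a1| / a0`,
#' and `phi = wrap_phase(arg(a1_flat) - arg(a1_sample))`. The sign is chosen
#' so retrieval inverts [simulate_phase_stepping()]. Elements whose zeroth
#' harmonic vanishes (dead pixels) are flagged in `mask` and set to neutral
#' sentinel values (`T = D = 1`, `phi = 0`).
#'
#' @param sample,flat `phase_stepping_stack`s with identical step phases.
#' @return A `retrieved_signals` object: matrices `T`, `D`, `phi`
#'   (wrapped to `(-pi, pi]`), logical `mask`, and the geometry.
#' @export
retrieve_signals <- function(sample, flat) {
  stopifnot(
    inherits(sample, "phase_stepping_stack"),
    inherits(flat, "phase_stepping_stack")
  )
  if (!isTRUE(all.equal(sample$step_phases, flat$step_phases))) {
    stop("sample and flat stacks must share step_phases")
  }
  if (!all(dim(sample$counts) == dim(flat$counts))) stop("stack shapes differ")
  n_steps <- dim(sample$counts)[1]
  if (n_steps < 3L) stop("n_steps must be >= 3")
  k <- sample$step_phases
  harm <- function(counts) {
    a0 <- apply(counts, c(2, 3), mean)
    er <- exp(-1i * k)
    a1 <- matrix(0i, dim(counts)[2], dim(counts)[3])
    for (j in seq_len(n_steps)) {
      a1 <- a1 + counts[j, , ] * er[j]
    }
    a1 <- 2 / n_steps * a1
    list(a0 = a0, a1 = a1)
  }
  hs <- harm(sample$counts)
  hf <- harm(flat$counts)
  dead <- hs$a0 <= 0 | hf$a0 <= 0
  a0s <- ifelse(dead, 1, hs$a0)
  a0f <- ifelse(dead, 1, hf$a0)
  Tmat <- a0s / a0f
  Vs <- Mod(hs$a1) / a0s
  Vf <- Mod(hf$a1) / a0f
  zeroV <- Vf <= 0
  D <- ifelse(zeroV, 1, Vs / pmax(Vf, .Machine$double.eps))
  phi <- wrap_phase(Arg(hf$a1) - Arg(hs$a1))
  Tmat[dead] <- 1
  D[dead] <- 1
  phi[dead] <- 0
  structure(
    list(T = Tmat, D = D, phi = phi, mask = dead, geometry = sample$geometry),
    class = "retrieved_signals"
  )
}

#' Extract the DPC sinogram from retrieved signals
#'
#' @param retrieved A [retrieve_signals()] result.
#' @return A `dpc_sinogram` carrying the dead-pixel mask.
#' @export
as_dpc_sinogram <- function(retrieved) {
  stopifnot(inherits(retrieved, "retrieved_signals"))
  dpc_sinogram(retrieved$phi, retrieved$geometry, mask = retrieved$mask)
}
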