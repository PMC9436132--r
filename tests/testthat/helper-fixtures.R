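# Shared fixtures. Everything is generated in code; the expensive objects
# (operator pairs, the trained denoiser) are built once per test run and
# memoised here.

.fixtures <- new.env(parent = emptyenv())

# canonical desk-scale study conditions used across the suite:
# 32x32 image, 48 angles, unit-rescaled delta, sensitivity 1 (strong edges
# wrap), 120000 flat counts per element and step, visibility 0.3
study_sensitivity <- function() 1
study_photons <- function() 120000
study_v0 <- function() 0.3

small_geometry <- function(n = 32, n_angles = 48, n_det = 47) {
  scan_geometry("parallel",
    n_angles = n_angles, n_det = n_det,
    det_pitch = 0.1, pixel_size = 0.1, image_shape = c(n, n)
  )
}

fan_geometry <- function(n = 24, n_angles = 36, n_det = 41) {
  scan_geometry("fan",
    n_angles = n_angles, n_det = n_det,
    det_pitch = 0.1, pixel_size = 0.1, image_shape = c(n, n),
    src_iso = 60, iso_det = 40
  )
}

fixture_op_kb <- function() {
  if (is.null(.fixtures$op_kb)) {
    .fixtures$op_kb <- dpc_operator(small_geometry(), sensitivity = study_sensitivity())
  }
  .fixtures$op_kb
}

fixture_op_fd <- function() {
  if (is.null(.fixtures$op_fd)) {
    .fixtures$op_fd <- fd_operator(small_geometry(), sensitivity = study_sensitivity())
  }
  .fixtures$op_fd
}

fixture_pairs <- function() {
  if (is.null(.fixtures$pairs)) {
    g <- small_geometry()
    phantoms <- lapply(seq_len(40), function(i) {
      make_breast_phantom(c(32, 32), 2 + (i %% 3), seed = 100 + i)
    })
    .fixtures$pairs <- generate_training_pairs(
      phantoms, g,
      sensitivity = study_sensitivity(),
      photons = study_photons(), V0 = study_v0(),
      seed = 5, op = fixture_op_kb()
    )
  }
  .fixtures$pairs
}

# the certified denoiser used by the denoiser, reconstruction and
# acceptance tests; trained once per run
fixture_denoiser <- function() {
  if (is.null(.fixtures$denoiser)) {
    .fixtures$denoiser <- train_denoiser(
      fixture_pairs(),
      denoiser_config(epochs = 80, seed = 11)
    )
  }
  .fixtures$denoiser
}

# noisy test-scan shared by the end-to-end comparisons (held out from the
# training seeds and phantom seeds)
fixture_test_scan <- function() {
  if (is.null(.fixtures$test_scan)) {
    g <- small_geometry()
    op <- fixture_op_kb()
    phantom <- make_breast_phantom(c(32, 32), 3, seed = 777)
    flats <- flat_field_maps(g, I0 = study_photons(), V0 = study_v0())
    sim <- simulate_phase_stepping(
      phantom, g,
      sensitivity = study_sensitivity(), flats = flats,
      photons = study_photons(), seed = 4242, op = op
    )
    ret <- retrieve_signals(sim$sample, sim$flat)
    .fixtures$test_scan <- list(
      phantom = phantom, sim = sim, retrieved = ret,
      phi = as_dpc_sinogram(ret)
    )
  }
  .fixtures$test_scan
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps), tol)
}
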