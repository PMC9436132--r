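test_that("data fidelity is a convex quadratic with the exact gradient", {
  op <- fixture_op_kb()
  ph <- make_breast_phantom(c(32, 32), 2, seed = 50)
  phi <- forward_project(ph, op)
  atmin <- data_fidelity_and_grad(ph$delta, phi, op)
  expect_lt(atmin$loss, 1e-20)
  expect_lt(max(abs(atmin$gradient)), 1e-12)

  set.seed(6)
  x <- matrix(rnorm(1024), 32)
  fg <- data_fidelity_and_grad(x, phi, op)
  for (k in 1:5) {
    d <- matrix(rnorm(1024), 32)
    d <- d / sqrt(sum(d^2))
    h <- 1e-5
    fd <- (data_fidelity_and_grad(x + h * d, phi, op)$loss -
      data_fidelity_and_grad(x - h * d, phi, op)$loss) / (2 * h)
    expect_rel_error(sum(fg$gradient * d), fd, 1e-5)
  }

  # midpoint convexity along random segments
  for (k in 1:3) {
    y <- matrix(rnorm(1024), 32)
    lm <- data_fidelity_and_grad((x + y) / 2, phi, op)$loss
    expect_lte(lm, (fg$loss + data_fidelity_and_grad(y, phi, op)$loss) / 2 + 1e-9)
  }

  # masked (dead-pixel) entries are excluded from loss and gradient
  mask <- matrix(FALSE, op$geometry$n_angles, op$geometry$n_det)
  mask[3, 5] <- TRUE
  phi_bad <- phi
  phi_bad$phi[3, 5] <- 1e6
  phi_bad$mask <- mask
  atmin2 <- data_fidelity_and_grad(ph$delta, phi_bad, op)
  expect_lt(atmin2$loss, 1e-20)
})

test_that("two-loop recursion reproduces Newton and dense BFGS oracles", {
  mem <- lbfgs_memory(10)
  g <- c(3, -2)
  expect_identical(lbfgs_direction(g, mem), -g)

  # single exact curvature pair on a 2x2 quadratic: one step hits the minimum
  H <- matrix(c(4, 1, 1, 2), 2)
  xstar <- c(1, -1)
  f_grad <- function(x) H %*% (x - xstar)
  x0 <- c(0, 0)
  x1 <- c(0.5, 0.2)
  mem <- lbfgs_push(mem, x1 - x0, f_grad(x1) - f_grad(x0))
  d <- lbfgs_direction(as.numeric(f_grad(x1)), mem)
  # with memory >= dimension and exact pairs, d = -H^{-1} g up to the
  # two-loop initial scaling; verify the step lands on the minimizer after
  # a second pair completes the curvature information
  x2 <- x1 + d
  mem <- lbfgs_push(mem, x2 - x1, f_grad(x2) - f_grad(x1))
  d2 <- lbfgs_direction(as.numeric(f_grad(x2)), mem)
  expect_lt(max(abs((x2 + d2) - xstar)), 1e-6)

  # 10-dim quadratic: full-memory two-loop equals dense BFGS
  set.seed(8)
  A <- crossprod(matrix(rnorm(100), 10)) + diag(10)
  b <- rnorm(10)
  grad <- function(x) A %*% x - b
  dense_B <- diag(10) # dense inverse-Hessian estimate (BFGS update)
  mem <- lbfgs_memory(20)
  x <- rnorm(10)
  gx <- as.numeric(grad(x))
  for (it in 1:12) {
    step <- 0.1
    x_new <- x - step * gx
    g_new <- as.numeric(grad(x_new))
    s <- x_new - x
    y <- g_new - gx
    rho <- 1 / sum(s * y)
    V <- diag(10) - rho * outer(s, y)
    dense_B <- V %*% dense_B %*% t(V) + rho * outer(s, s)
    mem <- lbfgs_push(mem, s, y)
    x <- x_new
    gx <- g_new
  }
  d_mem <- lbfgs_direction(gx, mem)
  d_dense <- -as.numeric(dense_B %*% gx)
  # identical up to the H0 scaling convention of the two-loop recursion
  gamma <- sum(mem$s[[12]] * mem$y[[12]]) / sum(mem$y[[12]]^2)
  dense_B0 <- gamma * diag(10)
  for (i in 1:12) {
    s <- mem$s[[i]]
    y <- mem$y[[i]]
    rho <- 1 / sum(s * y)
    V <- diag(10) - rho * outer(y, s)
    dense_B0 <- t(V) %*% dense_B0 %*% V + rho * outer(s, s)
  }
  expect_lt(max(abs(d_mem - (-as.numeric(dense_B0 %*% gx)))), 1e-8)
  # and it is always a descent direction
  expect_lt(sum(d_mem * gx), 0)

  # non-positive curvature pairs are rejected
  mem2 <- lbfgs_push(lbfgs_memory(5), c(1, 0), c(-1, 0))
  expect_identical(length(mem2$s), 0L)
})

test_that("PnP-L-BFGS is faithful to its outer/inner contract", {
  op <- fixture_op_kb()
  ph <- make_breast_phantom(c(32, 32), 2, seed = 51)
  phi <- forward_project(ph, op)

  # degenerate stop: eps_n = Inf returns after one denoise of the k_max iterate
  marker <- new.env()
  marker$calls <- 0L
  counting_denoiser <- function(img) {
    marker$calls <- marker$calls + 1L
    img
  }
  r0 <- pnp_lbfgs(phi, op, counting_denoiser, recon_config(k_max = 15, eps_n = Inf))
  expect_identical(r0$outer_count, 0L)
  expect_identical(marker$calls, 0L) # loss already below eps_n at the start

  r1 <- pnp_lbfgs(phi, op, counting_denoiser,
    recon_config(k_max = 15, eps_n = 1e-4, max_outer = 3)
  )
  expect_identical(marker$calls, r1$outer_count)
  # inner trace: exactly k_max loss values per outer iteration
  expect_true(all(table(r1$loss_trace$outer) == 15))

  # determinism
  r2 <- pnp_lbfgs(phi, op, NULL, recon_config(k_max = 15, eps_n = 1e-4, max_outer = 3))
  r3 <- pnp_lbfgs(phi, op, NULL, recon_config(k_max = 15, eps_n = 1e-4, max_outer = 3))
  expect_identical(r2$loss_trace, r3$loss_trace)
})

test_that("noise-free consistency: L-BFGS solves the quadratic, faster than GD", {
  g <- small_geometry(n = 16, n_angles = 24, n_det = 23)
  op <- dpc_operator(g, sensitivity = study_sensitivity())
  ph <- make_breast_phantom(c(16, 16), 1, seed = 9)
  phi <- forward_project(ph, op)

  rl <- pnp_lbfgs(phi, op, NULL, recon_config(k_max = 15, eps_n = 1e-6, max_outer = 200))
  expect_true(rl$converged)
  expect_gt(psnr(rl$delta_reg, ph$delta), 40)

  rg <- pnp_gd(phi, op, NULL, recon_config(k_max = 15, eps_n = 1e-6, max_outer = 600))
  expect_gt(rg$inner_count, rl$inner_count)

  # GD loss decreases monotonically under the Armijo backtracking
  expect_true(all(diff(rg$loss_trace$loss) <= 1e-12))

  # error-ratio decay over the final inner iterations (superlinear tendency):
  # for the quadratic data term the A-norm error is sqrt(2 * loss), so the
  # successive error ratios are sqrt(loss_{k+1} / loss_k)
  last <- rl$loss_trace$loss[rl$loss_trace$outer == max(rl$loss_trace$outer)]
  ratios <- sqrt(utils::tail(last, 6)[-1] / utils::tail(last, 6)[-6])
  expect_true(all(diff(ratios) < 0.1)) # eventually (weakly) decreasing
  expect_lt(mean(diff(ratios)), 0)

  # zero-gradient start (the all-zero image already solves phi = 0):
  # immediate stop without any update or denoise call
  phi0 <- dpc_sinogram(matrix(0, g$n_angles, g$n_det), g)
  rstat <- pnp_gd(phi0, op, NULL, recon_config(k_max = 15, eps_n = 1e-12, max_outer = 5))
  expect_true(rstat$converged)
  expect_identical(rstat$outer_count, 0L)
})

test_that("iterates remain bounded with a certified denoiser on noise-free data", {
  g <- small_geometry(n = 16, n_angles = 24, n_det = 23)
  op <- dpc_operator(g, sensitivity = study_sensitivity())
  ph <- make_breast_phantom(c(16, 16), 1, seed = 10)
  phi <- forward_project(ph, op)
  shrink <- function(img) 0.999 * img # certified non-expansive stand-in
  r <- pnp_lbfgs(phi, op, shrink, recon_config(k_max = 5, eps_n = 0, max_outer = 100))
  expect_lt(max(abs(r$delta_reg)), 10 * max(abs(ph$delta)))
})

test_that("Hilbert-filter FBP inverts the simulator on a disk", {
  n <- 64
  ps <- 3.2 / n
  g <- scan_geometry("parallel",
    n_angles = 360, n_det = 97, det_pitch = ps,
    pixel_size = ps, image_shape = c(n, n)
  )
  op <- dpc_operator(g, sensitivity = study_sensitivity())
  ph <- make_disk_phantom(c(n, n), 1, 1, pixel_size = ps, antialias = TRUE)
  sg <- forward_project(ph, op)
  rec <- fbp_hilbert(sg, sensitivity = study_sensitivity())
  expect_gt(psnr(rec, ph$delta, data_range = 1), 25)
  # residual is confined to the blob-blurred edge: interior is accurate
  xs <- (seq_len(n) - (n + 1) / 2) * ps
  r <- sqrt(outer(rev(xs)^2, xs^2, `+`))
  expect_lt(sqrt(mean((rec - ph$delta)[r < 0.7]^2)), 0.01)

  expect_true(all(fbp_hilbert(
    dpc_sinogram(matrix(0, 360, 97), g),
    sensitivity = 1
  ) == 0))
  # linearity in the sinogram
  s2 <- sg
  s2$phi <- 2 * sg$phi
  expect_lt(max(abs(fbp_hilbert(s2, sensitivity = 1) -
    2 * fbp_hilbert(sg, sensitivity = 1))), 1e-10)
  expect_error(fbp_hilbert(sg, fan_geometry()), "parallel")
})

test_that("Chambolle prox solves the ROF problem (reference cross-check)", {
  set.seed(11)
  x <- matrix(1, 8, 8) + matrix(rnorm(64, sd = 0.3), 8)
  w <- 0.15
  rof <- function(u) 0.5 * sum((u - x)^2) + w * total_variation(u)
  u <- chambolle_tv_prox(x, w, n_iter = 500)
  expect_lt(rof(u), rof(x)) # energy decreases
  expect_lt(sd(u), sd(x)) # closer to the constant

  # independent reference: scikit-image denoise_tv_chambolle on the same input
  xf <- tempfile(fileext = ".csv")
  uf <- tempfile(fileext = ".csv")
  write.table(x, xf, row.names = FALSE, col.names = FALSE, sep = ",")
  script <- sprintf(
    "import numpy as np; from skimage.restoration import denoise_tv_chambolle; x = np.loadtxt('%s', delimiter=','); np.savetxt('%s', denoise_tv_chambolle(x, weight=%g, max_num_iter=500), delimiter=',')",
    xf, uf, w
  )
  status <- system2("python", c("-c", shQuote(script)))
  expect_identical(status, 0L)
  u_ref <- as.matrix(read.table(uf, sep = ","))
  # same ROF objective value (iteration dialects differ slightly)
  expect_lt(abs(rof(u) - rof(unname(u_ref))) / rof(unname(u_ref)), 0.01)

  # weight -> 0 limit returns the input
  expect_lt(max(abs(chambolle_tv_prox(x, 1e-9, n_iter = 50) - x)), 1e-6)
  expect_error(chambolle_tv_prox(x, 0), "weight")
})

test_that("TV reconstruction beats FBP on piecewise-constant phantoms", {
  ts <- fixture_test_scan()
  op <- fixture_op_kb()
  fbp <- fbp_hilbert(ts$phi, sensitivity = study_sensitivity())
  tv <- suppressWarnings(tv_reconstruct(ts$phi, op,
    tv_weight = 0.3, n_outer = 12,
    config = recon_config(k_max = 15, eps_n = 0, max_outer = 12)
  ))
  expect_lt(total_variation(tv$delta_reg), total_variation(fbp))
  expect_gt(
    psnr(tv$delta_reg, ts$phantom$delta),
    psnr(fbp, ts$phantom$delta)
  )
})

test_that("postprocess_fbp composes FBP with the denoiser", {
  ts <- fixture_test_scan()
  fbp <- fbp_hilbert(ts$phi, sensitivity = study_sensitivity())
  out_id <- postprocess_fbp(ts$phi, denoiser = NULL, sensitivity = study_sensitivity())
  expect_identical(out_id, fbp)
  td <- fixture_denoiser()
  out <- postprocess_fbp(ts$phi, denoiser = td, sensitivity = study_sensitivity())
  expect_gt(psnr(out, ts$phantom$delta), psnr(fbp, ts$phantom$delta))
})

test_that("the noise floor estimate matches Monte-Carlo and scaling oracles", {
  g <- small_geometry(n = 16, n_angles = 12, n_det = 15)
  op <- dpc_operator(g, sensitivity = study_sensitivity())
  ph <- make_breast_phantom(c(16, 16), 1, seed = 13)

  # noiseless flats fit the stepping-curve model exactly: floor ~ 0
  sim0 <- simulate_phase_stepping(ph, g,
    sensitivity = study_sensitivity(),
    photons = 1e5, seed = 1, op = op, noiseless = TRUE
  )
  expect_lt(estimate_noise_level(sim0$flat), 1e-12)

  eps_at <- function(photons, seed) {
    sim <- simulate_phase_stepping(ph, g,
      sensitivity = study_sensitivity(),
      photons = photons, seed = seed, op = op
    )
    estimate_noise_level(sim$flat)
  }
  e1 <- mean(vapply(1:20, function(s) eps_at(20000, s), numeric(1)))
  e2 <- mean(vapply(1:20, function(s) eps_at(40000, s), numeric(1)))
  expect_lt(abs(e2 / e1 - 0.5), 0.1) # inverse-photon scaling within 20%

  # ground-truth oracle: expected retrieval-noise energy, measured as the
  # branch-aware (wrapped) difference between retrieved and true phase
  oracle <- mean(vapply(1:40, function(s) {
    sim <- simulate_phase_stepping(ph, g,
      sensitivity = study_sensitivity(),
      photons = 20000, seed = 100 + s, op = op
    )
    ret <- retrieve_signals(sim$sample, sim$flat)
    0.5 * sum(wrap_phase(ret$phi - sim$phi_true)^2)
  }, numeric(1)))
  expect_lt(abs(e1 - oracle) / oracle, 0.2)
})
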