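test_that("bias-free nets vanish at zero and are locally linear", {
  net <- bias_free_net(c(8, 8), input_shape = c(16, 16), seed = 3)
  expect_identical(max(abs(net_apply(net, matrix(0, 16, 16)))), 0)
  set.seed(1)
  img <- matrix(rnorm(256), 16)
  out <- net_apply(net, img)
  jm <- jacobian_row(net, img, c(5, 7))
  expect_rel_error(sum(jm * img), out[5, 7], 1e-10)
  jm2 <- jacobian_row(net, img, c(16, 16))
  expect_rel_error(sum(jm2 * img), out[16, 16], 1e-10)
  expect_error(jacobian_row(net, img, c(0, 5)), "out of bounds")
  # positive homogeneity underlying the training amplitude standardization
  expect_lt(max(abs(net_apply(net, 3.7 * img) - 3.7 * out)), 1e-10)
})

test_that("jacobian_row on linear single-layer stubs recovers the kernel", {
  # identity stub: 1x1 kernel = 1
  id_net <- structure(
    list(
      layers = list(list(kernel = array(1, c(1, 1, 1, 1)))),
      widths = c(1L, 1L), kernel_size = 1L, input_shape = c(8L, 8L)
    ),
    class = "bias_free_net"
  )
  jm <- jacobian_row(id_net, matrix(rnorm(64), 8), c(3, 4))
  expect_equal(sum(jm != 0), 1)
  expect_equal(jm[3, 4], 1)

  # mean-filter stub: uniform 3x3 kernel
  mean_net <- structure(
    list(
      layers = list(list(kernel = array(1 / 9, c(3, 3, 1, 1)))),
      widths = c(1L, 1L), kernel_size = 3L, input_shape = c(8L, 8L)
    ),
    class = "bias_free_net"
  )
  jm <- jacobian_row(mean_net, matrix(rnorm(64), 8), c(4, 4))
  expect_equal(sum(jm != 0), 9)
  expect_true(all(abs(jm[3:5, 3:5] - 1 / 9) < 1e-15))
})

test_that("power method matches a dense SVD oracle and simple stubs", {
  # identity and diagonal stubs via 1x1 kernels
  idk <- array(1, c(1, 1, 1, 1))
  expect_equal(layer_spectral_norm(idk, c(8, 8, 1), 50)$sigma, 1, tolerance = 1e-12)
  dk <- array(0, c(1, 1, 2, 2))
  dk[1, 1, 1, 1] <- 3
  dk[1, 1, 2, 2] <- 1
  expect_equal(layer_spectral_norm(dk, c(8, 8, 2), 200)$sigma, 3, tolerance = 1e-9)
  zk <- array(0, c(3, 3, 1, 1))
  expect_identical(layer_spectral_norm(zk, c(8, 8, 1), 10)$sigma, 0)

  # dense oracle: materialize the conv matrix column by column
  set.seed(7)
  K <- array(rnorm(9), c(3, 3, 1, 1))
  Amat <- matrix(0, 256, 256)
  for (i in 1:256) {
    e <- array(0, c(16, 16, 1))
    e[i] <- 1
    Amat[, i] <- as.vector(dpcct:::conv2d(e, K))
  }
  sv <- svd(Amat, nu = 0, nv = 0)$d[1]
  est <- layer_spectral_norm(K, c(16, 16, 1), n_iters = 20000)$sigma
  expect_rel_error(est, sv, 1e-6)

  # Rayleigh estimates are monotone non-decreasing in the iteration count
  sigmas <- vapply(c(1, 3, 10, 30, 100), function(it) {
    layer_spectral_norm(K, c(16, 16, 1), n_iters = it, seed = 5)$sigma
  }, numeric(1))
  expect_true(all(diff(sigmas) >= -1e-12))
})

test_that("the spectral hinge is zero exactly below the slack boundary", {
  st <- list(norms = c(0.5, 0.9))
  expect_identical(spectral_regularizer(NULL, st), 0)
  expect_equal(spectral_regularizer(NULL, list(norms = 2)), 1 + 1e-8)
  expect_identical(spectral_regularizer(NULL, list(norms = 1 - 1e-8)), 0)
})

test_that("training loss reduces to plain MSE and matches hand arithmetic", {
  id_net <- structure(
    list(
      layers = list(list(kernel = array(1, c(1, 1, 1, 1)))),
      widths = c(1L, 1L), kernel_size = 1L, input_shape = c(2L, 2L)
    ),
    class = "bias_free_net"
  )
  noisy <- matrix(c(1, 2, 3, 4), 2)
  pair_same <- list(noisy = noisy, clean = noisy)
  cfg0 <- denoiser_config(lambda_reg = 0)
  expect_identical(training_loss(id_net, list(pair_same), cfg0), 0)

  clean <- matrix(c(1, 2, 2, 6), 2)
  pair2 <- list(noisy = noisy, clean = clean)
  # identity net: per-pixel MSE = mean((noisy - clean)^2) = (0+0+1+4)/4
  expect_equal(training_loss(id_net, list(pair2), cfg0), 5 / 4)
  st <- list(norms = c(1.5))
  expect_equal(
    training_loss(id_net, list(pair2), denoiser_config(lambda_reg = 0.1), state = st),
    5 / 4 + 0.1 * (0.5 + 1e-8)
  )
  expect_error(training_loss(id_net, list(), cfg0), "nonempty")
})

test_that("mean-shift augmentation moves both members by one recorded offset", {
  p <- list(noisy = matrix(as.numeric(1:4), 2), clean = matrix(0, 2, 2), mean_offset = 0)
  p0 <- mean_shift_augment(p, c(0, 0), seed = 1)
  expect_identical(p0$noisy, p$noisy)
  expect_identical(p0$mean_offset, 0)

  p1 <- mean_shift_augment(p, c(-2, 2), seed = 9)
  expect_equal(p1$noisy - p$noisy, matrix(p1$mean_offset, 2, 2))
  expect_equal(p1$clean - p$clean, matrix(p1$mean_offset, 2, 2))
  # difference image is invariant
  expect_equal(p1$noisy - p1$clean, p$noisy - p$clean)

  offs <- vapply(1:2000, function(s) {
    mean_shift_augment(p, c(-1, 3), seed = s)$mean_offset
  }, numeric(1))
  ks <- suppressWarnings(ks.test(offs, "punif", -1, 3))
  expect_gt(ks$p.value, 0.01)
  expect_error(mean_shift_augment(p, c(2, 1)), "lo <= hi")
})

test_that("training pairs are deterministic and sit in the noisy-iterate band", {
  g <- small_geometry(n = 16, n_angles = 24, n_det = 23)
  op <- dpc_operator(g, sensitivity = study_sensitivity())
  phantoms <- lapply(1:3, function(i) make_breast_phantom(c(16, 16), 1, seed = 30 + i))

  pa <- generate_training_pairs(phantoms, g,
    sensitivity = study_sensitivity(),
    seed = 2, op = op
  )
  pb <- generate_training_pairs(phantoms, g,
    sensitivity = study_sensitivity(),
    seed = 2, op = op
  )
  expect_identical(pa, pb)

  # noiseless degenerate case: with data consistent (no Poisson noise and a
  # sensitivity low enough that no sinogram entry wraps) the iterate stays
  # at the clean minimizer
  op_mild <- dpc_operator(g, sensitivity = 0.3)
  sim_chk <- simulate_phase_stepping(phantoms[[1]], g,
    sensitivity = 0.3,
    seed = 2, op = op_mild, noiseless = TRUE
  )
  expect_lt(max(abs(sim_chk$phi_true)), pi) # consistency precondition
  pn <- generate_training_pairs(phantoms[1], g,
    sensitivity = 0.3,
    seed = 2, op = op_mild, noiseless = TRUE
  )
  expect_gt(psnr(pn[[1]]$noisy, pn[[1]]$clean), 60)

  # with counting noise at the study conditions, the 15-update iterates land
  # in a finite corruption band (regression bound measured on this pipeline)
  ps <- vapply(fixture_pairs(), function(p) psnr(p$noisy, p$clean), numeric(1))
  expect_true(all(ps > 3 & ps < 25))
})

test_that("training certifies non-expansiveness and still denoises", {
  td <- fixture_denoiser()
  expect_lte(td$spectral_state$product, 1 + 1e-3)
  expect_identical(nrow(td$log) >= 10, TRUE)

  # Eq-style chain bound audited from below
  el <- empirical_lipschitz(td$net, n_pairs = 200, seed = 3)
  expect_lte(el, td$spectral_state$product + 1e-9)

  # denoising improves held-out pairs on average
  pairs <- fixture_pairs()
  ids <- vapply(pairs, function(p) p$id, numeric(1))
  val <- pairs[ids > quantile(ids, 0.8)]
  dp <- vapply(val, function(p) {
    psnr(net_apply(td$net, p$noisy), p$clean) - psnr(p$noisy, p$clean)
  }, numeric(1))
  expect_gt(mean(dp), 0)

  # approximate mean-shift invariance over the trained range
  p <- val[[1]]
  base <- psnr(net_apply(td$net, p$noisy), p$clean)
  for (c_shift in c(-0.25, 0.25)) {
    shifted <- psnr(net_apply(td$net, p$noisy + c_shift), p$clean + c_shift)
    expect_lt(abs(shifted - base), 1)
  }
})

test_that("scaled identity stubs bound the empirical Lipschitz ratio exactly", {
  id_net <- structure(
    list(
      layers = list(list(kernel = array(1, c(1, 1, 1, 1)))),
      widths = c(1L, 1L), kernel_size = 1L, input_shape = c(8L, 8L)
    ),
    class = "bias_free_net"
  )
  expect_equal(empirical_lipschitz(id_net, n_pairs = 20, seed = 2, n_local = 2), 1,
    tolerance = 1e-9
  )
  half_net <- id_net
  half_net$layers[[1]]$kernel[] <- 0.5
  expect_equal(empirical_lipschitz(half_net, n_pairs = 20, seed = 2, n_local = 2), 0.5,
    tolerance = 1e-9
  )
})
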