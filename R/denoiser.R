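#' Denoiser training configuration
#'
#' @param lambda_reg Weight of the spectral-norm product regularizer
#'   (default 1e-4).
#' @param epsilon Hinge slack of the regularizer (default 1e-8).
#' @param power_iters Warm-started power iterations per training step.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param seed RNG seed for shuffling, initialization and augmentation.
#' @param mean_shift_range Range of the random global mean shift applied to
#'   each pair at presentation time; `NULL` defaults to plus/minus half the
#'   clean-image dynamic range of the training set (after amplitude
#'   standardization).
#' @param image_scale Standardized training amplitude: pairs are rescaled so
#'   the largest clean dynamic range equals this value before training.
#'   Because the bias-free ReLU network is positively homogeneous
#'   (`f(c x) = c f(x)` for `c > 0`), the trained map is unchanged on data of
#'   any amplitude; the standardization only fixes the balance between the
#'   supervised term and the spectral hinge so the regularizer weight has a
#'   scale-free meaning.
#' @param val_frac Fraction of phantoms held out for validation.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param cert_epochs Cap on the certification-phase epochs run after early
#'   stopping (same loss, converged norm estimates, learning rate / 10)
#'   until the certified spectral-norm product is at most 1.
#' @param channels,kernel_size Network architecture (see [bias_free_net()]).
#' @return A `denoiser_config`.
#' @export
denoiser_config <- function(lambda_reg = 1e-4, epsilon = 1e-8, power_iters = 2,
                            epochs = 150, batch_size = 5, lr = 1e-3, seed = 1,
                            mean_shift_range = NULL, val_frac = 0.2,
                            patience = 25, channels = c(16, 16),
                            kernel_size = 3, image_scale = 0.01,
                            cert_epochs = 15) {
  if (lambda_reg < 0) stop("lambda_reg must be >= 0")
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must lie in (0, 1)")
  structure(
    list(
      lambda_reg = lambda_reg, epsilon = epsilon,
      power_iters = as.integer(power_iters), epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), lr = lr, seed = seed,
      mean_shift_range = mean_shift_range, val_frac = val_frac,
      patience = as.integer(patience), channels = channels,
      kernel_size = kernel_size, image_scale = image_scale,
      cert_epochs = as.integer(cert_epochs)
    ),
    class = "denoiser_config"
  )
}

#' Build training pairs from noisy unregularized iterates
#'
#' For each clean phantom, simulates a Poisson-noisy phase-stepping
#' acquisition, retrieves the (possibly wrapped) DPC sinogram, and runs
#' `n_updates` updates of the unregularized optimization scheme (the same
#' L-BFGS data updates the reconstruction uses, with no denoising step)
#' starting AT the clean phantom. Because the retrieved data are wrapped
#' and Poisson-noisy while the start point is the clean image, the iterate
#' accumulates exactly the propagated noise and wrapping artifacts the
#' Plug-and-Play denoiser will meet during reconstruction, and becomes the
#' noisy member of the pair.
#'
#' @param phantoms List of `phantom_image`s.
#' @param geometry A [scan_geometry()].
#' @param sensitivity Interferometer spec or scalar sensitivity.
#' @param n_updates Unregularized gradient updates (default 15).
#' @param photons Mean flat counts per element per step.
#' @param V0 Flat-field visibility.
#' @param n_steps Phase steps.
#' @param seed Base RNG seed (per-phantom seeds derive from it).
#' @param op Optional pre-built operator pair.
#' @param noiseless Build noise-free pairs (degenerate control).
#' @return List of `training_pair`s: `list(noisy, clean, mean_offset, id)`.
#' @export
generate_training_pairs <- function(phantoms, geometry, sensitivity = 1,
                                    n_updates = 15, photons = 120000,
                                    V0 = 0.3, n_steps = 5, seed = 1,
                                    op = NULL, noiseless = FALSE) {
  if (n_updates < 1) stop("n_updates must be >= 1")
  if (is.null(op)) op <- dpc_operator(geometry, sensitivity = sensitivity)
  flats <- flat_field_maps(geometry, I0 = photons, V0 = V0, Phi0 = 0)
  pairs <- list()
  for (idx in seq_along(phantoms)) {
    ph <- phantoms[[idx]]
    sim <- simulate_phase_stepping(
      ph, geometry,
      sensitivity = sensitivity, flats = flats,
      n_steps = n_steps, photons = photons,
      seed = seed + 1000L * idx, op = op, noiseless = noiseless
    )
    phi <- as_dpc_sinogram(retrieve_signals(sim$sample, sim$flat))
    loss0 <- data_fidelity_and_grad(ph$delta, phi, op)$loss
    blk <- inner_data_updates(
      ph$delta, phi, op,
      recon_config(k_max = n_updates), method = "lbfgs"
    )
    if (!is.finite(blk$final_loss) || blk$final_loss > 10 * max(loss0, 1e-12)) {
      message("training pair ", idx, " rejected: diverging data updates")
      next
    }
    pairs[[length(pairs) + 1L]] <- structure(
      list(noisy = blk$x, clean = ph$delta, mean_offset = 0, id = idx),
      class = "training_pair"
    )
  }
  pairs
}

#' Shift the global mean of a training pair
#'
#' Adds one scalar offset, drawn uniformly from `range`, to both members.
#' The denoising target stays consistent (clean + offset) while the local
#' mean the network sees is decoupled from the artifact content --
#' emulating the drifting local means of intermediate DPC iterates.
#'
#' @param pair A `training_pair`.
#' @param range `c(lo, hi)` of the uniform offset.
#' @param seed RNG seed.
#' @return The shifted pair with `mean_offset` recording the applied shift.
#' @export
mean_shift_augment <- function(pair, range, seed = 1) {
  if (range[1] > range[2]) stop("range must satisfy lo <= hi")
  off <- with_seed(seed, stats::runif(1, range[1], range[2]))
  pair$noisy <- pair$noisy + off
  pair$clean <- pair$clean + off
  pair$mean_offset <- pair$mean_offset + off
  pair
}

#' Denoiser training loss
#'
#' Mean squared error (per pixel, averaged over the batch) between
#' `f(noisy)` and `clean`, plus `lambda_reg` times the spectral-norm
#' product hinge ([spectral_regularizer()]).
#'
#' @param net A `bias_free_net`.
#' @param batch List of `training_pair`s.
#' @param config A [denoiser_config()].
#' @param state Optional `spectral_state`; computed fresh if missing.
#' @return Scalar loss.
#' @export
training_loss <- function(net, batch, config = denoiser_config(), state = NULL) {
  if (!length(batch)) stop("batch must be nonempty")
  mse <- 0
  for (p in batch) {
    if (!all(dim(p$noisy) == dim(p$clean))) stop("pair members have mismatched shapes")
    e <- net_apply(net, p$noisy) - p$clean
    mse <- mse + mean(e^2)
  }
  mse <- mse / length(batch)
  reg <- 0
  if (config$lambda_reg > 0) {
    if (is.null(state)) state <- certify_spectral_norms(net, n_iters = 50)
    reg <- spectral_regularizer(net, state, config$epsilon)
  }
  mse + config$lambda_reg * reg
}

#' Train the certified non-expansive bias-free denoiser
#'
#' Minimizes [training_loss()] with Adam: the supervised denoising term on
#' noisy-iterate/clean pairs (mean-shift augmented at presentation time)
#' plus the spectral-norm product hinge, whose gradient flows through the
#' power-iteration singular vectors of each layer. Per-layer norm estimates
#' are warm-started across steps; training stops early when the validation
#' MSE stops improving. After training the shipped weights are certified
#' with a converged (default 1000-iteration) power method.
#'
#' @param pairs List of `training_pair`s (>= 2; split by phantom into
#'   train/validation).
#' @param config A [denoiser_config()].
#' @return A `trained_denoiser`: `list(net, spectral_state, log, config)`
#'   where `log` is a per-epoch data frame (losses, per-layer norms,
#'   product).
#' @export
train_denoiser <- function(pairs, config = denoiser_config()) {
  if (length(pairs) < 2) stop("need at least 2 pairs for a train/validation split")
  ids <- vapply(pairs, function(p) p$id %||% NA_integer_, numeric(1))
  uid <- unique(ids)
  n_val <- max(1L, floor(config$val_frac * length(uid)))
  val_ids <- utils::tail(uid, n_val)
  val <- pairs[ids %in% val_ids]
  train <- pairs[!(ids %in% val_ids)]
  if (!length(train)) stop("validation split consumed all pairs")

  # amplitude standardization (see denoiser_config); the shipped network is
  # scale-equivariant, so this never needs undoing at inference time
  dyn0 <- max(vapply(train, function(p) max(p$clean) - min(p$clean), numeric(1)))
  sc <- if (dyn0 > 0) config$image_scale / dyn0 else 1
  rescale_pair <- function(p) {
    p$noisy <- p$noisy * sc
    p$clean <- p$clean * sc
    p
  }
  train <- lapply(train, rescale_pair)
  val <- lapply(val, rescale_pair)

  shape <- dim(train[[1]]$clean)
  net <- bias_free_net(
    channels = config$channels, kernel_size = config$kernel_size,
    input_shape = shape, seed = config$seed
  )
  nl <- length(net$layers)

  msr <- config$mean_shift_range
  if (is.null(msr)) {
    dr <- max(vapply(train, function(p) max(p$clean) - min(p$clean), numeric(1)))
    msr <- c(-0.5, 0.5) * dr
  }

  adam_m <- lapply(net$layers, function(l) array(0, dim(l$kernel)))
  adam_v <- lapply(net$layers, function(l) array(0, dim(l$kernel)))
  b1 <- 0.9
  b2 <- 0.999
  adam_eps <- 1e-8
  t_step <- 0L

  sn_states <- lapply(seq_len(nl), function(l) NULL)
  layer_norms <- function(iters) {
    out <- numeric(nl)
    for (l in seq_len(nl)) {
      sn <- layer_spectral_norm(
        net$layers[[l]]$kernel, c(shape, net$widths[l]),
        n_iters = iters, state = sn_states[[l]], seed = config$seed + 10L * l
      )
      sn_states[[l]] <<- sn
      out[l] <- sn$sigma
    }
    out
  }

  val_mse <- function() {
    if (!length(val)) {
      return(NA_real_)
    }
    tot <- 0
    for (p in val) {
      e <- net_apply(net, p$noisy) - p$clean
      tot <- tot + mean(e^2)
    }
    tot / length(val)
  }

  log_rows <- list()
  best_val <- Inf
  best_net <- net
  stall <- 0L

  # one full pass over the training set; the certification phase reuses it
  # with a reduced learning rate and converged norm estimates
  do_epoch <- function(lr_use, pi_use) {
    ord <- sample(length(train))
    ep_loss <- 0
    n_batches <- 0L
    for (b0 in seq(1, length(train), by = config$batch_size)) {
      bidx <- ord[b0:min(b0 + config$batch_size - 1L, length(train))]
      grads <- lapply(net$layers, function(l) array(0, dim(l$kernel)))
      bl <- 0
      for (bi in bidx) {
        p <- train[[bi]]
        off <- stats::runif(1, msr[1], msr[2])
        noisy <- p$noisy + off
        clean <- p$clean + off
        cache <- net_forward(net, noisy, keep = TRUE)
        e <- matrix(cache$out, shape[1]) - clean
        bl <- bl + mean(e^2)
        bk <- net_backward(net, cache, 2 * e / (length(bidx) * length(e)))
        for (l in seq_len(nl)) grads[[l]] <- grads[[l]] + bk$kernel_grads[[l]]
      }
      bl <- bl / length(bidx)

      # spectral hinge gradient through the power-iteration vectors:
      # d sigma_l / dK = outer(u_l, v_l) in convolution-parameter space
      norms <- layer_norms(pi_use)
      prod_n <- prod(norms)
      if (config$lambda_reg > 0 && prod_n > 1 - config$epsilon) {
        for (l in seq_len(nl)) {
          sn <- sn_states[[l]]
          if (is.null(sn$u) || sn$sigma == 0) next
          dsig <- conv2d_kernel_grad(
            sn$v, sn$u, net$kernel_size, net$kernel_size
          )
          grads[[l]] <- grads[[l]] + config$lambda_reg * (prod_n / norms[l]) * dsig
        }
      }

      t_step <<- t_step + 1L
      for (l in seq_len(nl)) {
        adam_m[[l]] <<- b1 * adam_m[[l]] + (1 - b1) * grads[[l]]
        adam_v[[l]] <<- b2 * adam_v[[l]] + (1 - b2) * grads[[l]]^2
        mhat <- adam_m[[l]] / (1 - b1^t_step)
        vhat <- adam_v[[l]] / (1 - b2^t_step)
        net$layers[[l]]$kernel <<- net$layers[[l]]$kernel -
          lr_use * mhat / (sqrt(vhat) + adam_eps)
      }
      ep_loss <- ep_loss + bl + config$lambda_reg *
        max(0, prod_n - (1 - config$epsilon))
      n_batches <- n_batches + 1L
      if (!is.finite(ep_loss)) stop("training loss became non-finite; aborting")
    }
    ep_loss / n_batches
  }

  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ep_loss <- do_epoch(config$lr, config$power_iters)
      norms_ep <- layer_norms(30L)
      vm <- val_mse()
      log_rows[[ep]] <- data.frame(
        epoch = ep, phase = "train", train_loss = ep_loss, val_mse = vm,
        product = prod(norms_ep),
        t(stats::setNames(norms_ep, paste0("norm_l", seq_len(nl))))
      )
      if (is.finite(vm) && vm < best_val - 1e-12) {
        best_val <- vm
        best_net <- net
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }

    # certification phase: the warm few-iteration norm estimates used above
    # lag the converged values by ~1% on clustered conv spectra, so the
    # hinge can equilibrate marginally above 1. Continue minimizing the SAME
    # loss at a reduced learning rate with converged per-layer norms until
    # the certified product is non-expansive.
    net <- best_net
    sn_states[seq_len(nl)] <- list(NULL)
    if (config$lambda_reg > 0) {
      for (cp in seq_len(config$cert_epochs)) {
        st <- certify_spectral_norms(net, n_iters = 300, seed = config$seed)
        if (st$product <= 1 - config$epsilon / 2) break
        ep_loss <- do_epoch(config$lr / 10, 100L)
        norms_ep <- layer_norms(100L)
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          epoch = length(log_rows) + 1L, phase = "certify",
          train_loss = ep_loss, val_mse = val_mse(),
          product = prod(norms_ep),
          t(stats::setNames(norms_ep, paste0("norm_l", seq_len(nl))))
        )
      }
    }
  })

  state <- certify_spectral_norms(net, n_iters = 1000, seed = config$seed)
  if (config$lambda_reg > 0 && state$product > 1 + 1e-3) {
    warning(sprintf(
      "certified spectral-norm product %.4f exceeds 1; the denoiser is not non-expansive",
      state$product
    ))
  }
  structure(
    list(
      net = net, spectral_state = state,
      log = do.call(rbind, log_rows), config = config,
      best_val_mse = best_val
    ),
    class = "trained_denoiser"
  )
}

#' @export
print.trained_denoiser <- function(x, ...) {
  cat(sprintf(
    "<trained_denoiser> %d epochs logged, best val MSE %.4g\n",
    nrow(x$log), x$best_val_mse
  ))
  print(x$net)
  print(x$spectral_state)
  invisible(x)
}
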