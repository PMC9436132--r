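#' Reconstruction configuration
#'
#' @param k_max Inner data updates per outer iteration (default 15).
#' @param eps_n Stopping threshold on the data loss `0.5 * ||A d - phi||^2`;
#'   the expected noise floor of the data (see [estimate_noise_level()]).
#' @param max_outer Safety cap on outer iterations.
#' @param c_armijo Armijo sufficient-decrease constant of the backtracking
#'   line search.
#' @param max_backtracks Maximum halvings per line search.
#' @param memory Optional L-BFGS memory capacity; default `k_max - 1` (full
#'   inner-loop history, matching the restart-every-outer structure).
#' @param seed RNG seed recorded with the run.
#' @return A `recon_config` list.
#' @export
recon_config <- function(k_max = 15, eps_n = 0, max_outer = 50,
                         c_armijo = 1e-4, max_backtracks = 60,
                         memory = NULL, seed = 1) {
  k_max <- as.integer(k_max)
  if (k_max < 1L) stop("k_max must be >= 1")
  if (eps_n < 0) stop("eps_n must be >= 0")
  structure(
    list(
      k_max = k_max, eps_n = eps_n, max_outer = as.integer(max_outer),
      c_armijo = c_armijo, max_backtracks = as.integer(max_backtracks),
      memory = as.integer(memory %||% (k_max - 1L)), seed = seed
    ),
    class = "recon_config"
  )
}

#' Data-fidelity loss and gradient
#'
#' The convex quadratic data term of DPC reconstruction,
#' `L = 0.5 * ||A delta - phi||^2`, and its gradient `A'(A delta - phi)`.
#' Masked sinogram entries (dead pixels) are excluded from both.
#'
#' @param delta Image matrix (or `phantom_image`).
#' @param phi A `dpc_sinogram` or matrix.
#' @param op A `dpc_operator_pair`.
#' @return `list(loss, gradient)` with the gradient as an image matrix.
#' @export
data_fidelity_and_grad <- function(delta, phi, op) {
  img <- as_image_matrix(delta)
  stop_if_not_finite(img, "delta")
  m <- if (inherits(phi, "dpc_sinogram")) phi$phi else phi
  stop_if_not_finite(m, "phi")
  mask <- if (inherits(phi, "dpc_sinogram")) phi$mask else NULL
  r <- as.numeric(op$A %*% as.vector(img)) - as.vector(t(m))
  if (!is.null(mask)) {
    r[as.vector(t(mask))] <- 0
  }
  g <- as.numeric(Matrix::crossprod(op$A, r))
  list(
    loss = 0.5 * sum(r^2),
    gradient = matrix(g, nrow = op$geometry$image_shape[1])
  )
}

#' L-BFGS search direction by the two-loop recursion
#'
#' Standard limited-memory inverse-Hessian application. An empty memory
#' returns the steepest-descent direction; the initial inverse-Hessian
#' scaling uses the most recent curvature pair. The returned direction is
#' guaranteed to be a descent direction (falls back to `-gradient` if the
#' recursion ever loses that property numerically).
#'
#' @param gradient Gradient vector (or matrix, flattened).
#' @param memory An `lbfgs_memory` from [lbfgs_memory()].
#' @return Descent direction with the same shape as `gradient`.
#' @export
lbfgs_direction <- function(gradient, memory) {
  g <- as.vector(gradient)
  n <- length(memory$s)
  if (n == 0L) {
    d <- -g
  } else {
    q <- g
    alpha <- numeric(n)
    for (i in n:1) {
      alpha[i] <- memory$rho[[i]] * sum(memory$s[[i]] * q)
      q <- q - alpha[i] * memory$y[[i]]
    }
    gamma <- sum(memory$s[[n]] * memory$y[[n]]) / sum(memory$y[[n]]^2)
    r <- gamma * q
    for (i in 1:n) {
      beta <- memory$rho[[i]] * sum(memory$y[[i]] * r)
      r <- r + memory$s[[i]] * (alpha[i] - beta)
    }
    d <- -r
    if (sum(d * g) >= 0) d <- -g
  }
  if (is.matrix(gradient)) matrix(d, nrow = nrow(gradient)) else d
}

#' Create an empty L-BFGS curvature memory
#'
#' @param capacity Maximum number of stored `(s, y)` pairs.
#' @return An `lbfgs_memory`.
#' @export
lbfgs_memory <- function(capacity = 14) {
  structure(
    list(s = list(), y = list(), rho = list(), capacity = as.integer(capacity)),
    class = "lbfgs_memory"
  )
}

#' Admit a curvature pair into an L-BFGS memory
#'
#' Pairs violating the curvature condition `s'y > tol * |s||y|` are rejected
#' (the quadratic DPC data term always satisfies it away from round-off).
#'
#' @param memory An `lbfgs_memory`.
#' @param s Iterate difference.
#' @param y Gradient difference.
#' @return The updated memory (pairs beyond capacity are dropped oldest-first).
#' @export
lbfgs_push <- function(memory, s, y) {
  s <- as.vector(s)
  y <- as.vector(y)
  sy <- sum(s * y)
  if (!(sy > 1e-12 * sqrt(sum(s^2)) * sqrt(sum(y^2)))) {
    return(memory)
  }
  memory$s[[length(memory$s) + 1L]] <- s
  memory$y[[length(memory$y) + 1L]] <- y
  memory$rho[[length(memory$rho) + 1L]] <- 1 / sy
  while (length(memory$s) > memory$capacity) {
    memory$s[[1]] <- NULL
    memory$y[[1]] <- NULL
    memory$rho[[1]] <- NULL
  }
  memory
}

# One block of k_max data updates from x0 with a fresh L-BFGS memory
# (or plain gradient descent when method = "gd"). Backtracking Armijo line
# search with unit initial step (1/|g| on the very first steepest-descent
# step). Returns the iterate, the per-update loss values and the total
# number of updates taken.
inner_data_updates <- function(x0, phi, op, config, method = c("lbfgs", "gd"),
                               loss_target = -Inf) {
  method <- match.arg(method)
  x <- as.vector(as_image_matrix(x0))
  mem <- lbfgs_memory(config$memory)
  fg <- data_fidelity_and_grad(matrix(x, nrow = op$geometry$image_shape[1]), phi, op)
  losses <- numeric(0)
  g_prev <- NULL
  x_prev <- NULL
  k <- 0L
  while (k < config$k_max) {
    g <- as.vector(fg$gradient)
    loss <- fg$loss
    losses <- c(losses, loss)
    if (k > 0L && method == "lbfgs") {
      mem <- lbfgs_push(mem, x - x_prev, g - g_prev)
    }
    d <- if (method == "lbfgs") lbfgs_direction(g, mem) else -g
    gd <- sum(g * d)
    if (gd >= 0 || sqrt(sum(g^2)) == 0) {
      # stationary point: nothing left to descend
      break
    }
    step <- if (method == "gd" || length(mem$s) == 0L) {
      gn <- sqrt(sum(g^2))
      min(1, 1 / gn)
    } else {
      1
    }
    x_prev <- x
    g_prev <- g
    accepted <- FALSE
    for (bt in seq_len(config$max_backtracks)) {
      x_try <- x + step * d
      fg_try <- data_fidelity_and_grad(
        matrix(x_try, nrow = op$geometry$image_shape[1]), phi, op
      )
      if (fg_try$loss <= loss + config$c_armijo * step * gd) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    x <- x_try
    fg <- fg_try
    k <- k + 1L
    if (fg$loss < loss_target) break
  }
  list(
    x = matrix(x, nrow = op$geometry$image_shape[1]),
    losses = losses, final_loss = fg$loss, updates = k
  )
}

make_recon_result <- function(delta_reg, trace, outer_count, inner_count,
                              converged, config, method) {
  structure(
    list(
      delta_reg = delta_reg, loss_trace = trace,
      outer_count = outer_count, inner_count = inner_count,
      converged = converged, config = config, method = method
    ),
    class = "dpc_recon"
  )
}

#' @export
print.dpc_recon <- function(x, ...) {
  cat(sprintf(
    "<dpc_recon> %s: %d outer / %d inner updates, final data loss %.4g%s\n",
    x$method, x$outer_count, x$inner_count,
    utils::tail(x$loss_trace$loss, 1),
    if (x$converged) "" else " (max_outer reached)"
  ))
  invisible(x)
}

#' Plot the data-loss trace of an iterative reconstruction
#'
#' @param x A `dpc_recon` result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_loss_trace <- function(x, ...) {
  stopifnot(inherits(x, "dpc_recon"))
  graphics::plot(
    seq_len(nrow(x$loss_trace)), x$loss_trace$loss,
    log = "y", type = "l", xlab = "data update", ylab = "0.5 ||A d - phi||^2", ...
  )
  invisible(x)
}

# resolve the denoising step: NULL/"identity" -> identity, a function, or a
# trained bias-free network
as_denoiser_fun <- function(denoiser, warn_uncertified = TRUE) {
  if (is.null(denoiser) || identical(denoiser, "identity")) {
    return(identity)
  }
  if (is.function(denoiser)) {
    return(denoiser)
  }
  if (inherits(denoiser, "trained_denoiser")) {
    prod <- denoiser$spectral_state$product
    if (warn_uncertified && is.finite(prod) && prod > 1 + 1e-3) {
      warning(sprintf(
        "denoiser is not certified non-expansive (spectral-norm product %.4f > 1)",
        prod
      ))
    }
    net <- denoiser$net
    return(function(img) net_apply(net, img))
  }
  if (inherits(denoiser, "bias_free_net")) {
    return(function(img) net_apply(denoiser, img))
  }
  stop("denoiser must be NULL, a function, a bias_free_net or a trained_denoiser")
}

#' Plug-and-Play reconstruction with L-BFGS data updates
#'
#' Alternates blocks of `k_max` L-BFGS updates of the quadratic data term
#' with one application of the denoiser, restarting the quasi-Newton memory
#' at every outer iteration, until the data loss falls below `eps_n` (the
#' noise floor) or `max_outer` is reached. The iteration starts from the
#' all-zero image; from the second outer iteration on, each inner block
#' starts at the previous denoised iterate.
#'
#' @param phi A `dpc_sinogram`.
#' @param op A `dpc_operator_pair`.
#' @param denoiser `NULL`/"identity", a function `image -> image`, or a
#'   [train_denoiser()] result (a warning is issued if its certified
#'   spectral-norm product exceeds 1).
#' @param config A [recon_config()].
#' @return A `dpc_recon`: the denoised final iterate `delta_reg`, a
#'   per-update loss trace (`data.frame(outer, inner, loss)`), counters and
#'   the configuration snapshot.
#' @export
pnp_lbfgs <- function(phi, op, denoiser = NULL, config = recon_config()) {
  run_pnp(phi, op, denoiser, config, method = "lbfgs")
}

#' Plug-and-Play reconstruction with gradient-descent data updates
#'
#' First-order control for [pnp_lbfgs()]: identical outer structure with
#' the search direction fixed to the negative gradient (backtracking step).
#'
#' @inheritParams pnp_lbfgs
#' @return A `dpc_recon`.
#' @export
pnp_gd <- function(phi, op, denoiser = NULL, config = recon_config()) {
  run_pnp(phi, op, denoiser, config, method = "gd")
}

run_pnp <- function(phi, op, denoiser, config, method) {
  stopifnot(inherits(config, "recon_config"))
  fdn <- as_denoiser_fun(denoiser)
  shape <- op$geometry$image_shape
  delta <- matrix(0, shape[1], shape[2])
  delta_reg <- delta
  trace <- list()
  i <- 0L
  inner_total <- 0L
  converged <- FALSE
  repeat {
    start_loss <- data_fidelity_and_grad(delta, phi, op)$loss
    if (start_loss < config$eps_n) {
      converged <- TRUE
      if (i == 0L) delta_reg <- delta
      break
    }
    if (i >= config$max_outer) break
    if (i > 0L) delta <- delta_reg
    blk <- inner_data_updates(delta, phi, op, config, method = method)
    delta <- blk$x
    delta_reg <- fdn(delta)
    trace[[i + 1L]] <- data.frame(
      outer = i + 1L, inner = seq_along(blk$losses), loss = blk$losses
    )
    inner_total <- inner_total + blk$updates
    i <- i + 1L
    # a whole block of data updates that cannot decrease the loss means the
    # iterate has reached the floor the prior permits
    if (length(blk$losses) && blk$final_loss >= blk$losses[1]) {
      warning("data loss did not decrease across an outer iteration; stopping early")
      break
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else data.frame(outer = integer(0), inner = integer(0), loss = numeric(0))
  make_recon_result(delta_reg, trace, i, inner_total, converged, config, paste0("pnp_", method))
}

#' Estimate the data-loss noise floor from a flat stack
#'
#' Estimates the per-element variance of the retrieved differential phase
#' from the flat stack's own stepping-curve residuals. Per detector
#' element, the two-harmonic model `I_j = a0 + Re(a1 e^{i k_j})` is fitted
#' (exactly the retrieval's harmonics); the residual variance over the
#' steps (`n_steps - 3` degrees of freedom) estimates the count variance,
#' which propagates through the phase retrieval by the delta method as
#' `var(arg a1) = 2 s^2 / (n_steps |a1|^2)` per stack. Sample and flat
#' stacks contribute one such term each (assuming transmission near 1 and
#' no sample dark-field -- weakly attenuating specimens), and the expected
#' data loss at the true image is `eps_n = 0.5 * sum(var(phi))`. Noiseless
#' stacks fit the model exactly and return 0; Poisson stacks return a floor
#' that scales inversely with the photon count. Deterministic (no
#' resampling).
#'
#' @param flat A `phase_stepping_stack` of flat-field counts.
#' @return Scalar `eps_n`.
#' @export
estimate_noise_level <- function(flat) {
  stopifnot(inherits(flat, "phase_stepping_stack"))
  n_steps <- dim(flat$counts)[1]
  if (n_steps < 4) {
    warning("n_steps <= 3 leaves no residual degrees of freedom; eps_n may be unreliable")
  }
  k <- flat$step_phases
  a0 <- apply(flat$counts, c(2, 3), mean)
  a1 <- matrix(0i, dim(flat$counts)[2], dim(flat$counts)[3])
  for (j in seq_len(n_steps)) a1 <- a1 + flat$counts[j, , ] * exp(-1i * k[j])
  a1 <- 2 / n_steps * a1
  rss <- matrix(0, dim(flat$counts)[2], dim(flat$counts)[3])
  for (j in seq_len(n_steps)) {
    fit <- a0 + Re(a1 * exp(1i * k[j]))
    rss <- rss + (flat$counts[j, , ] - fit)^2
  }
  s2 <- rss / max(1L, n_steps - 3L)
  a1sq <- pmax(Mod(a1)^2, .Machine$double.eps)
  var_phi <- 2 * (2 * s2 / (n_steps * a1sq)) # sample + flat contributions
  0.5 * sum(var_phi)
}
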