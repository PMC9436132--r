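# Bias-free convolutional network primitives.
#
# All layers are plain 2D cross-correlations with 'same' zero padding and NO
# additive constants anywhere, so the network is positively homogeneous and
# f(0) = 0 holds bit-exactly. Convolutions run as im2col patch matrices times
# reshaped kernels (BLAS), which is fast enough at desk scale.

# x: H x W x Cin array; K: kh x kw x Cin x Cout. Returns H x W x Cout.
conv2d <- function(x, K) {
  kh <- dim(K)[1]
  kw <- dim(K)[2]
  cin <- dim(K)[3]
  cout <- dim(K)[4]
  H <- dim(x)[1]
  W <- dim(x)[2]
  P <- im2col(x, kh, kw)
  out <- P %*% matrix(K, kh * kw * cin, cout)
  array(out, c(H, W, cout))
}

# adjoint of conv2d in its input argument: correlation with the spatially
# flipped kernel and swapped channel axes (exact transpose under zero 'same'
# padding)
conv2d_adjoint <- function(y, K) {
  kh <- dim(K)[1]
  kw <- dim(K)[2]
  Kt <- aperm(K[kh:1, kw:1, , , drop = FALSE], c(1, 2, 4, 3))
  conv2d(y, Kt)
}

# gradient of sum(gout * conv2d(x, K)) with respect to K
conv2d_kernel_grad <- function(x, gout, kh, kw) {
  cin <- dim(x)[3]
  cout <- dim(gout)[3]
  H <- dim(x)[1]
  W <- dim(x)[2]
  P <- im2col(x, kh, kw)
  G <- crossprod(P, matrix(gout, H * W, cout))
  array(G, c(kh, kw, cin, cout))
}

# (H*W) x (kh*kw*Cin) patch matrix with zero 'same' padding; column order is
# (i fastest, then j, then channel), matching matrix(K, ...) reshaping
im2col <- function(x, kh, kw) {
  H <- dim(x)[1]
  W <- dim(x)[2]
  cin <- dim(x)[3]
  ph <- (kh - 1) %/% 2
  pw <- (kw - 1) %/% 2
  xp <- array(0, c(H + kh - 1L, W + kw - 1L, cin))
  xp[ph + seq_len(H), pw + seq_len(W), ] <- x
  P <- matrix(0, H * W, kh * kw * cin)
  col <- 0L
  for (cc in seq_len(cin)) {
    for (j in seq_len(kw)) {
      for (i in seq_len(kh)) {
        col <- col + 1L
        P[, col] <- xp[i:(i + H - 1L), j:(j + W - 1L), cc]
      }
    }
  }
  P
}

#' Construct a bias-free ReLU denoising network
#'
#' A stack of 3x3 convolutional layers with ReLU between them (never after
#' the last) and no bias terms anywhere, so `f(0) = 0` exactly and the
#' network is locally linear: for every input there is a Jacobian `J(x)`
#' with `f(x) = J(x) x`. Kernels are He-initialized, then each layer is
#' rescaled to a spectral norm of `init_norm` (measured by power iteration
#' on `input_shape`), so training starts from a certified-contractive
#' configuration.
#'
#' @param channels Hidden channel widths, e.g. `c(16, 16)` gives a
#'   1 -> 16 -> 16 -> 1 network of depth 3.
#' @param kernel_size Odd spatial kernel size.
#' @param input_shape Image shape used for initial spectral normalization.
#' @param init_norm Per-layer spectral norm after initialization.
#' @param seed RNG seed.
#' @return A `bias_free_net`.
#' @export
bias_free_net <- function(channels = c(16, 16), kernel_size = 3,
                          input_shape = c(32, 32), init_norm = 0.9, seed = 1) {
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
  widths <- c(1L, as.integer(channels), 1L)
  layers <- with_seed(seed, {
    lapply(seq_len(length(widths) - 1L), function(l) {
      cin <- widths[l]
      cout <- widths[l + 1L]
      fan_in <- kernel_size^2 * cin
      K <- array(
        stats::rnorm(kernel_size^2 * cin * cout, sd = sqrt(2 / fan_in)),
        c(kernel_size, kernel_size, cin, cout)
      )
      list(kernel = K)
    })
  })
  net <- structure(
    list(
      layers = layers, widths = widths, kernel_size = as.integer(kernel_size),
      input_shape = as.integer(input_shape)
    ),
    class = "bias_free_net"
  )
  if (is.finite(init_norm) && init_norm > 0) {
    for (l in seq_along(net$layers)) {
      sn <- layer_spectral_norm(net$layers[[l]]$kernel,
        input_shape = c(input_shape, widths[l]), n_iters = 50, seed = seed + l
      )
      if (sn$sigma > 0) {
        net$layers[[l]]$kernel <- net$layers[[l]]$kernel * (init_norm / sn$sigma)
      }
    }
  }
  net
}

#' @export
print.bias_free_net <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$kernel), numeric(1)))
  cat(sprintf(
    "<bias_free_net> depth %d (%s), %d parameters, %dx%d kernels, no biases\n",
    length(x$layers), paste(x$widths, collapse = "-"), np,
    x$kernel_size, x$kernel_size
  ))
  invisible(x)
}

# forward pass; keep = TRUE retains layer inputs and pre-activations for
# backprop
net_forward <- function(net, x, keep = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  nl <- length(net$layers)
  inputs <- vector("list", nl)
  pre <- vector("list", nl)
  a <- x
  for (l in seq_len(nl)) {
    if (keep) inputs[[l]] <- a
    z <- conv2d(a, net$layers[[l]]$kernel)
    if (keep) pre[[l]] <- z
    a <- if (l < nl) pmax(z, 0) else z
  }
  if (keep) list(out = a, inputs = inputs, pre = pre) else a
}

#' Apply a bias-free network to an image
#'
#' @param net A `bias_free_net`.
#' @param img Image matrix.
#' @return Denoised image matrix.
#' @export
net_apply <- function(net, img) {
  stopifnot(is.matrix(img))
  out <- net_forward(net, img)
  matrix(out, nrow = nrow(img))
}

# backprop: returns kernel gradients and (optionally) the input gradient for
# a given output cotangent gout (H x W x 1 array or matrix)
net_backward <- function(net, cache, gout, want_input_grad = FALSE) {
  if (is.matrix(gout)) gout <- array(gout, c(dim(gout), 1L))
  nl <- length(net$layers)
  gk <- vector("list", nl)
  g <- gout
  for (l in nl:1) {
    if (l < nl) {
      g <- g * (cache$pre[[l]] > 0)
    }
    K <- net$layers[[l]]$kernel
    gk[[l]] <- conv2d_kernel_grad(cache$inputs[[l]], g, dim(K)[1], dim(K)[2])
    if (l > 1L || want_input_grad) {
      g <- conv2d_adjoint(g, K)
    }
  }
  list(kernel_grads = gk, input_grad = if (want_input_grad) g else NULL)
}

#' Spectral norm of a convolutional layer by the power method
#'
#' Power iteration on the composed map `W* W` acting on full input tensors
#' (zero 'same' padding included), returning the leading singular-value
#' estimate. The Rayleigh-quotient estimates are monotone non-decreasing in
#' the iteration count up to float tolerance. Warm starting from a previous
#' state makes the few-iteration estimates used during training cheap and
#' accurate.
#'
#' @param kernel `kh x kw x cin x cout` array (or a layer list with a
#'   `$kernel`).
#' @param input_shape `(H, W, cin)` of the layer input.
#' @param n_iters Power iterations (>= 1).
#' @param state Optional previous return value to warm-start from.
#' @param seed Seed for the random start when no state is given.
#' @return `list(sigma, v, u)`: the norm estimate and the leading right/left
#'   singular-vector estimates (unit norm).
#' @export
layer_spectral_norm <- function(kernel, input_shape, n_iters = 100,
                                state = NULL, seed = 1) {
  if (is.list(kernel)) kernel <- kernel$kernel
  n_iters <- max(1L, as.integer(n_iters))
  v <- if (!is.null(state) && !is.null(state$v) &&
    all(dim(state$v) == input_shape)) {
    state$v
  } else {
    with_seed(seed, array(stats::rnorm(prod(input_shape)), input_shape))
  }
  nv <- sqrt(sum(v^2))
  if (nv == 0) {
    return(list(sigma = 0, v = v, u = NULL))
  }
  v <- v / nv
  sigma <- 0
  u <- NULL
  for (it in seq_len(n_iters)) {
    u <- conv2d(v, kernel)
    sigma <- sqrt(sum(u^2))
    if (sigma == 0) {
      return(list(sigma = 0, v = v, u = u))
    }
    v_new <- conv2d_adjoint(u / sigma, kernel)
    nv <- sqrt(sum(v_new^2))
    if (nv == 0) break
    v <- v_new / nv
  }
  u <- conv2d(v, kernel)
  sigma <- sqrt(sum(u^2))
  list(sigma = sigma, v = v, u = if (sigma > 0) u / sigma else u)
}

#' Certify all layer spectral norms of a network
#'
#' Runs a converged power method (default 1000 iterations) on every layer
#' and returns the per-layer norms and their product -- the certified upper
#' bound on the network's Lipschitz constant (composition bound; ReLU is
#' 1-Lipschitz and does not enter the product).
#'
#' @param net A `bias_free_net`.
#' @param n_iters Power iterations per layer.
#' @param state Optional previous `spectral_state` to warm-start from.
#' @param seed RNG seed for cold starts.
#' @return A `spectral_state`: `list(norms, product, vectors, n_iters)`.
#' @export
certify_spectral_norms <- function(net, n_iters = 1000, state = NULL, seed = 1) {
  shape <- net$input_shape
  norms <- numeric(length(net$layers))
  vecs <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    st <- if (!is.null(state)) list(v = state$vectors[[l]]$v) else NULL
    sn <- layer_spectral_norm(
      net$layers[[l]]$kernel,
      input_shape = c(shape, net$widths[l]),
      n_iters = n_iters, state = st, seed = seed + l
    )
    norms[l] <- sn$sigma
    vecs[[l]] <- sn
  }
  structure(
    list(norms = norms, product = prod(norms), vectors = vecs, n_iters = n_iters),
    class = "spectral_state"
  )
}

#' @export
print.spectral_state <- function(x, ...) {
  cat(sprintf(
    "<spectral_state> layer norms: %s | product %.6f\n",
    paste(sprintf("%.3f", x$norms), collapse = ", "), x$product
  ))
  invisible(x)
}

#' Spectral-norm product regularizer
#'
#' The hinge `R = max(0, prod_l L(W_l) - (1 - epsilon))`: zero exactly when
#' the product of the per-layer spectral norms is at most `1 - epsilon`, so
#' any minimizer certifies the network non-expansive through the
#' composition bound.
#'
#' @param net A `bias_free_net` (unused beyond arity; the product comes from
#'   `state`).
#' @param state A `spectral_state` (or any list with `$norms`).
#' @param epsilon Slack (default 1e-8).
#' @return Scalar regularizer value.
#' @export
spectral_regularizer <- function(net, state, epsilon = 1e-8) {
  prod_norms <- prod(state$norms)
  max(0, prod_norms - (1 - epsilon))
}

#' Row of the network Jacobian at an input
#'
#' Gradient of one output pixel with respect to the whole input image. For
#' a bias-free ReLU network the map is locally linear, so the inner product
#' of this weight map with the input reproduces the output pixel exactly
#' (up to float round-off) -- the interpretability identity of bias-free
#' denoisers.
#'
#' @param net A `bias_free_net`.
#' @param image Input image matrix.
#' @param pixel `c(row, col)` of the output pixel.
#' @return Weight-map matrix of the same shape as `image`.
#' @export
jacobian_row <- function(net, image, pixel) {
  stopifnot(is.matrix(image))
  if (pixel[1] < 1 || pixel[1] > nrow(image) || pixel[2] < 1 || pixel[2] > ncol(image)) {
    stop("pixel coordinate out of bounds")
  }
  cache <- net_forward(net, image, keep = TRUE)
  gout <- matrix(0, nrow(image), ncol(image))
  gout[pixel[1], pixel[2]] <- 1
  bk <- net_backward(net, cache, gout, want_input_grad = TRUE)
  matrix(bk$input_grad, nrow = nrow(image))
}

#' Empirical Lipschitz ratio of a network
#'
#' Evaluates `||f(x1) - f(x2)|| / ||x1 - x2||` on random Gaussian pairs and
#' additionally runs a local Jacobian power iteration (exact for the
#' piecewise-linear ReLU network within an activation region) at random
#' points, returning the maximum ratio found. Used to audit the certified
#' spectral-norm product bound from below.
#'
#' @param net A `bias_free_net`.
#' @param n_pairs Number of random pairs (>= 1).
#' @param seed RNG seed.
#' @param shape Image shape for the probes.
#' @param n_local Points at which the local Jacobian norm is estimated.
#' @param local_iters Power iterations per local estimate.
#' @return Maximum empirical ratio.
#' @export
empirical_lipschitz <- function(net, n_pairs = 100, seed = 1, shape = NULL,
                                n_local = 10, local_iters = 30) {
  shape <- shape %||% net$input_shape
  with_seed(seed, {
    best <- 0
    for (p in seq_len(n_pairs)) {
      x1 <- matrix(stats::rnorm(prod(shape)), shape[1])
      x2 <- x1 + matrix(stats::rnorm(prod(shape), sd = stats::runif(1, 0.01, 1)), shape[1])
      dn <- sqrt(sum((x1 - x2)^2))
      if (dn == 0) next
      r <- sqrt(sum((net_apply(net, x1) - net_apply(net, x2))^2)) / dn
      best <- max(best, r)
    }
    # local operator norm of the Jacobian at random points: J v by forward
    # differencing (exact within a linear region), J' u by backprop
    h <- 1e-4
    for (p in seq_len(n_local)) {
      x <- matrix(stats::rnorm(prod(shape)), shape[1])
      fx <- net_apply(net, x)
      v <- matrix(stats::rnorm(prod(shape)), shape[1])
      v <- v / sqrt(sum(v^2))
      sig <- 0
      for (it in seq_len(local_iters)) {
        Jv <- (net_apply(net, x + h * v) - fx) / h
        sig <- sqrt(sum(Jv^2))
        if (sig == 0) break
        cache <- net_forward(net, x, keep = TRUE)
        JTu <- net_backward(net, cache, Jv / sig, want_input_grad = TRUE)$input_grad
        nv <- sqrt(sum(JTu^2))
        if (nv == 0) break
        v <- matrix(JTu / nv, shape[1])
      }
      best <- max(best, sig)
    }
    best
  })
}
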