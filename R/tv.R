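#' Total-variation proximal step (Chambolle dual projection)
#'
#' Solves the ROF problem
#' `argmin_u 0.5 * ||u - x||^2 + weight * TV(u)` with isotropic TV by
#' Chambolle's fixed-point iteration on the dual field (step 0.25, the
#' classical stability bound for the 2D discrete gradient).
#'
#' @param x Input image matrix.
#' @param weight TV weight (> 0).
#' @param n_iter Dual iterations.
#' @param tol Early-exit tolerance on the dual increment.
#' @return Denoised image matrix.
#' @export
chambolle_tv_prox <- function(x, weight, n_iter = 100, tol = 1e-6) {
  if (weight <= 0) stop("weight must be > 0")
  nr <- nrow(x)
  nc <- ncol(x)
  p1 <- matrix(0, nr, nc) # dual field, row direction
  p2 <- matrix(0, nr, nc) # dual field, col direction
  tau <- 0.25
  div_p <- matrix(0, nr, nc)
  # forward-difference gradient with Neumann boundary
  grad <- function(u) {
    list(
      g1 = rbind(u[-1, , drop = FALSE] - u[-nr, , drop = FALSE], rep(0, nc)),
      g2 = cbind(u[, -1, drop = FALSE] - u[, -nc, drop = FALSE], rep(0, nr))
    )
  }
  # divergence: negative adjoint of the forward-difference gradient
  divg <- function(q1, q2) {
    d1 <- q1
    if (nr > 2) d1[2:(nr - 1), ] <- q1[2:(nr - 1), ] - q1[1:(nr - 2), ]
    d1[nr, ] <- -q1[nr - 1, ]
    d2 <- q2
    if (nc > 2) d2[, 2:(nc - 1)] <- q2[, 2:(nc - 1)] - q2[, 1:(nc - 2)]
    d2[, nc] <- -q2[, nc - 1]
    d1 + d2
  }
  for (it in seq_len(n_iter)) {
    gr <- grad(div_p - x / weight)
    denom <- 1 + tau * sqrt(gr$g1^2 + gr$g2^2)
    p1 <- (p1 + tau * gr$g1) / denom
    p2 <- (p2 + tau * gr$g2) / denom
    div_new <- divg(p1, p2)
    dmax <- max(abs(div_new - div_p)) * weight
    div_p <- div_new
    if (dmax < tol) break
  }
  x - weight * div_p
}

#' Isotropic total variation of an image
#'
#' @param x Image matrix.
#' @return Scalar TV value (forward differences, Neumann boundary).
#' @export
total_variation <- function(x) {
  nr <- nrow(x)
  nc <- ncol(x)
  g1 <- rbind(x[-1, , drop = FALSE] - x[-nr, , drop = FALSE], rep(0, nc))
  g2 <- cbind(x[, -1, drop = FALSE] - x[, -nc, drop = FALSE], rep(0, nr))
  sum(sqrt(g1^2 + g2^2))
}

#' Iterative reconstruction with a TV prior
#'
#' The classical baseline: the same alternating structure as [pnp_lbfgs()]
#' with the denoising step replaced by the TV proximal operator
#' ([chambolle_tv_prox()]).
#'
#' @param phi A `dpc_sinogram`.
#' @param op A `dpc_operator_pair` (the finite-difference pair reproduces
#'   the classical algorithm; any pair is accepted).
#' @param tv_weight TV weight of the proximal step (> 0).
#' @param n_outer Number of outer (data-block + prox) iterations.
#' @param config A [recon_config()]; `eps_n` stops early as in PnP.
#' @param prox_iter Chambolle iterations per prox application.
#' @return A `dpc_recon`.
#' @export
tv_reconstruct <- function(phi, op, tv_weight, n_outer = 10,
                           config = recon_config(max_outer = n_outer),
                           prox_iter = 80) {
  if (tv_weight <= 0) stop("tv_weight must be > 0")
  config$max_outer <- as.integer(n_outer)
  prox <- function(img) chambolle_tv_prox(img, weight = tv_weight, n_iter = prox_iter)
  res <- run_pnp(phi, op, prox, config, method = "lbfgs")
  res$method <- "tv"
  res
}
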