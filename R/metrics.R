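#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)`. Identical images give `Inf` (flagged
#' with an attribute rather than an error).
#'
#' @param x Image under test.
#' @param ref Reference image.
#' @param data_range Peak-to-peak range of the reference; default
#'   `max(ref) - min(ref)`.
#' @return PSNR in dB; `Inf` with attribute `flagged = "zero-mse"` when the
#'   images are identical.
#' @export
psnr <- function(x, ref, data_range = NULL) {
  stopifnot(all(dim(x) == dim(ref)))
  data_range <- data_range %||% (max(ref) - min(ref))
  if (data_range <= 0) stop("data_range must be > 0")
  mse <- mean((x - ref)^2)
  if (mse == 0) {
    return(structure(Inf, flagged = "zero-mse"))
  }
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index
#'
#' Mean SSIM with a uniform sliding window (default 7x7) and sample
#' covariance normalization, matching the common reference implementation;
#' the window and stabilization constants are part of the return value's
#' attributes so reports are unambiguous.
#'
#' @param x,ref Images of equal shape.
#' @param data_range Dynamic range of the data; default from `ref`.
#' @param win_size Odd window side length.
#' @param K1,K2 Stabilization constants.
#' @return Mean SSIM (scalar in `[-1, 1]`).
#' @export
ssim <- function(x, ref, data_range = NULL, win_size = 7, K1 = 0.01, K2 = 0.03) {
  stopifnot(all(dim(x) == dim(ref)))
  if (win_size %% 2 != 1 || win_size < 3) stop("win_size must be odd and >= 3")
  data_range <- data_range %||% (max(ref) - min(ref))
  if (data_range <= 0) stop("data_range must be > 0")
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  NP <- win_size^2
  cov_norm <- NP / (NP - 1) # sample covariance
  ux <- uniform_filter(x, win_size)
  uy <- uniform_filter(ref, win_size)
  uxx <- uniform_filter(x * x, win_size)
  uyy <- uniform_filter(ref * ref, win_size)
  uxy <- uniform_filter(x * ref, win_size)
  vx <- cov_norm * (uxx - ux^2)
  vy <- cov_norm * (uyy - uy^2)
  vxy <- cov_norm * (uxy - ux * uy)
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  pad <- (win_size - 1) / 2
  nr <- nrow(x)
  nc <- ncol(x)
  core <- S[(pad + 1):(nr - pad), (pad + 1):(nc - pad)]
  structure(mean(core), win_size = win_size, K1 = K1, K2 = K2)
}

# moving-average filter with nearest-edge padding (matches the reflective
# behaviour only away from borders; SSIM is averaged over the valid core,
# so the border handling never enters the score)
uniform_filter <- function(x, win) {
  pad <- (win - 1) / 2
  nr <- nrow(x)
  nc <- ncol(x)
  ri <- c(rep(1, pad), seq_len(nr), rep(nr, pad))
  ci <- c(rep(1, pad), seq_len(nc), rep(nc, pad))
  xp <- x[ri, ci, drop = FALSE]
  # integral image with a zero guard row/column
  S <- matrix(0, nrow(xp) + 1L, ncol(xp) + 1L)
  S[-1, -1] <- t(apply(apply(xp, 2, cumsum), 1, cumsum))
  i <- seq_len(nr)
  j <- seq_len(nc)
  out <- S[i + win, j + win, drop = FALSE] - S[i, j + win, drop = FALSE] -
    S[i + win, j, drop = FALSE] + S[i, j, drop = FALSE]
  out / win^2
}

#' Region-of-interest SNR and CNR
#'
#' `snr = mean(roi1) / sd(roi1)` and
#' `cnr = |mean(roi1) - mean(roi2)| / sqrt((var(roi1) + var(roi2)) / 2)`
#' over two non-overlapping pixel rectangles. The exact definitions are
#' attached to the result so every report states them.
#'
#' @param x Image matrix.
#' @param roi1,roi2 Integer vectors `c(row_min, row_max, col_min, col_max)`.
#' @return `list(snr, cnr, definitions)`; zero-variance ROIs flag the
#'   affected metric as `Inf`.
#' @export
snr_cnr <- function(x, roi1, roi2) {
  get_roi <- function(r) {
    stopifnot(length(r) == 4, r[1] >= 1, r[3] >= 1, r[2] <= nrow(x), r[4] <= ncol(x),
              r[1] <= r[2], r[3] <= r[4])
    x[r[1]:r[2], r[3]:r[4]]
  }
  overlap <- !(roi1[2] < roi2[1] || roi2[2] < roi1[1] ||
    roi1[4] < roi2[3] || roi2[4] < roi1[3])
  if (overlap) stop("roi1 and roi2 must not overlap")
  a <- get_roi(roi1)
  b <- get_roi(roi2)
  sda <- stats::sd(as.vector(a))
  snr <- if (sda == 0) structure(Inf, flagged = "zero-variance") else mean(a) / sda
  pooled <- sqrt((stats::var(as.vector(a)) + stats::var(as.vector(b))) / 2)
  cnr <- if (pooled == 0) {
    structure(Inf, flagged = "zero-variance")
  } else {
    abs(mean(a) - mean(b)) / pooled
  }
  list(
    snr = snr, cnr = cnr,
    definitions = c(
      snr = "mean(roi1)/sd(roi1)",
      cnr = "|mean(roi1)-mean(roi2)|/sqrt((var(roi1)+var(roi2))/2)"
    )
  )
}

#' Collect a metric report for a reconstruction
#'
#' @param x Reconstruction.
#' @param ref Ground-truth image.
#' @param roi1,roi2 ROI rectangles for SNR/CNR (see [snr_cnr()]).
#' @param data_range PSNR/SSIM range; default from `ref`.
#' @return A `metric_report` list with `psnr`, `ssim`, `snr`, `cnr` and the
#'   ROI/metric definitions.
#' @export
metric_report <- function(x, ref, roi1, roi2, data_range = NULL) {
  sc <- snr_cnr(x, roi1, roi2)
  structure(
    list(
      psnr = psnr(x, ref, data_range),
      ssim = as.numeric(ssim(x, ref, data_range)),
      snr = sc$snr, cnr = sc$cnr,
      roi1 = roi1, roi2 = roi2, definitions = sc$definitions
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> PSNR %.2f dB | SSIM %.4f | SNR %.2f | CNR %.2f\n",
    x$psnr, x$ssim, x$snr, x$cnr
  ))
  cat("  ", x$definitions["snr"], "; ", x$definitions["cnr"], "\n", sep = "")
  invisible(x)
}
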