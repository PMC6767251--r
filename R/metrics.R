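check_same_shape <- function(ref, est) {
  if (!identical(dim(ref), dim(est))) stop("image shapes differ")
  invisible(TRUE)
}

#' Root mean squared error
#'
#' `sqrt(sum((ref - est)^2) / N)` over all N pixels.
#'
#' @param ref,est Numeric matrices of equal shape (reference first).
#' @return Scalar RMSE (`>= 0`; homogeneous of degree 1 under joint scaling).
#' @export
rmse <- function(ref, est) {
  check_same_shape(ref, est)
  sqrt(mean((ref - est)^2))
}

#' Normalised mean absolute distance
#'
#' `sum |ref - est| / sum |ref|`: the summed absolute deviation relative to
#' the summed absolute reference (invariant under joint scaling).
#'
#' @param ref,est Numeric matrices of equal shape; `sum(abs(ref))` must be
#'   positive.
#' @return Scalar NMAD (`>= 0`; 1 when `est` is identically zero).
#' @export
nmad <- function(ref, est) {
  check_same_shape(ref, est)
  denom <- sum(abs(ref))
  if (denom == 0) stop("all-zero reference image")
  sum(abs(ref - est)) / denom
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(max(ref)^2 / MSE)` in dB, with the peak taken as the reference
#' image's actual maximum. Identical images give `Inf`.
#'
#' @param ref,est Numeric matrices of equal shape.
#' @return Scalar PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(ref, est) {
  check_same_shape(ref, est)
  mse <- mean((ref - est)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(ref)^2 / mse)
}

gaussian_kernel_1d <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Valid-mode separable Gaussian filtering via banded matrix products.
gauss_filter_valid <- function(img, k) {
  n <- length(k)
  hr <- nrow(img) - n + 1; hc <- ncol(img) - n + 1
  Br <- matrix(0, hr, nrow(img))
  for (i in seq_len(hr)) Br[i, i:(i + n - 1)] <- k
  Bc <- matrix(0, hc, ncol(img))
  for (i in seq_len(hc)) Bc[i, i:(i + n - 1)] <- k
  Br %*% img %*% t(Bc)
}

#' Structural similarity index
#'
#' Standard windowed SSIM with an 11 x 11 Gaussian window (sigma 1.5),
#' default constants `K1 = 0.01`, `K2 = 0.03` and data range `max(ref)`,
#' averaged over all (valid) window positions. Always `<= 1`, with 1 for
#' identical images.
#'
#' @param ref,est Numeric matrices of equal shape, at least 11 x 11.
#' @param data_range Dynamic range L (default `max(ref)`).
#' @return Scalar mean SSIM.
#' @export
ssim <- function(ref, est, data_range = max(ref)) {
  check_same_shape(ref, est)
  stopifnot(nrow(ref) >= 11, ncol(ref) >= 11)
  k <- gaussian_kernel_1d()
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mu_x <- gauss_filter_valid(ref, k)
  mu_y <- gauss_filter_valid(est, k)
  sxx <- gauss_filter_valid(ref * ref, k) - mu_x^2
  syy <- gauss_filter_valid(est * est, k) - mu_y^2
  sxy <- gauss_filter_valid(ref * est, k) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(s)
}

#' All four reconstruction-quality metrics
#'
#' @param ref Ground-truth image.
#' @param est Reconstructed image.
#' @return List of class `metrics_report` with `rmse`, `nmad`, `psnr`,
#'   `ssim` and `n_pixels`.
#' @export
metrics_report <- function(ref, est) {
  structure(list(rmse = rmse(ref, est), nmad = nmad(ref, est),
                 psnr = psnr(ref, est), ssim = ssim(ref, est),
                 n_pixels = length(ref)),
            class = "metrics_report")
}
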