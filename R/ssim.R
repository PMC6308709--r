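#' Structural similarity index between two images
#'
#' Standard SSIM with the canonical parameters: local statistics under an
#' 11 x 11 Gaussian-weighted window (sigma = 1.5), stabilizers
#' C1 = (0.01 * 255)^2 and C2 = (0.03 * 255)^2, the SSIM map averaged over
#' all fully-interior window positions, and the three channels averaged with
#' equal weight. The measure is symmetric in its arguments and equals 1
#' exactly for identical images.
#'
#' @param a,b Images of identical dimensions: H x W x 3 arrays (or plain
#'   H x W matrices for a single channel) on the [0, 255] scale.
#' @return A number in [-1, 1].
#' @export
#' @examples
#' img <- gen_synthetic_image(24, 32, k = 3, noise = 10)
#' compute_ssim(img, img) # 1
compute_ssim <- function(a, b) {
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1))
  if (is.matrix(b)) b <- array(b, dim = c(dim(b), 1))
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("dimension mismatch: %s vs %s",
                  paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  if (dim(a)[1] < 11 || dim(a)[2] < 11) {
    abort("images must be at least 11 x 11 for the standard SSIM window")
  }
  mean(vapply(seq_len(dim(a)[3]), function(ch) {
    ssim_channel(a[, , ch], b[, , ch])
  }, numeric(1)))
}

# Separable valid-mode convolution with a normalized 1-D Gaussian
# (radius 5, sigma 1.5), applied down rows then across columns.
gauss_kernel_1d <- function(sigma = 1.5, radius = 5L) {
  x <- seq(-radius, radius)
  w <- exp(-(x^2) / (2 * sigma^2))
  w / sum(w)
}

conv_valid <- function(m, w) {
  r <- length(w)
  hh <- nrow(m) - r + 1L
  acc <- matrix(0, hh, ncol(m))
  for (t in seq_len(r)) acc <- acc + w[t] * m[t:(t + hh - 1L), , drop = FALSE]
  ww <- ncol(m) - r + 1L
  out <- matrix(0, hh, ww)
  for (t in seq_len(r)) out <- out + w[t] * acc[, t:(t + ww - 1L), drop = FALSE]
  out
}

ssim_channel <- function(x, y, data_range = 255) {
  w <- gauss_kernel_1d()
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mx <- conv_valid(x, w)
  my <- conv_valid(y, w)
  sxx <- conv_valid(x * x, w) - mx * mx
  syy <- conv_valid(y * y, w) - my * my
  sxy <- conv_valid(x * y, w) - mx * my
  s <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
       ((mx * mx + my * my + c1) * (sxx + syy + c2))
  mean(s)
}
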