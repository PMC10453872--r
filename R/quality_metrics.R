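# Image-quality metrics used to evaluate the preprocessing stages.

check_pair <- function(a, b) {
  stopifnot_image(a)
  stopifnot_image(b)
  if (!same_geometry(a, b)) {
    stop("images must have identical shape and value range")
  }
}

#' Mean squared error between two images
#'
#' Mean of squared per-pixel differences over all pixels and channels; 0 iff
#' the images are identical.
#'
#' @param a,b [ImageTensor-class] objects with identical shape and range.
#' @return nonnegative scalar.
#' @export
mse <- function(a, b) {
  check_pair(a, b)
  mean((a@pixels - b@pixels)^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(maxValue^2 / mse(a, b))`; `Inf` for identical images. The
#' reference peak defaults to the top of the declared value range.
#'
#' @param a,b [ImageTensor-class] objects with identical shape and range.
#' @param maxValue peak signal value (default: the declared range top).
#' @return PSNR in dB (`Inf` when MSE is 0).
#' @export
psnr <- function(a, b, maxValue = a@valueRange[2L]) {
  check_pair(a, b)
  if (maxValue <= 0) stop("maxValue must be positive")
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(maxValue^2 / m)
}

# 2-D Gaussian window, 11 x 11, sigma 1.5, normalized to sum 1
ssim_window <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# valid-region windowed local mean via the C++ convolution kernel
ssim_filter <- function(m, w) {
  x <- array(m, c(dim(m), 1L, 1L))
  W <- array(w, c(dim(w), 1L, 1L))
  .cpp_conv2d_fwd(x, W, 0, 1L, 0L)[, , 1L, 1L]
}

#' Structural similarity index
#'
#' Mean local SSIM with the canonical parameters: 11 x 11 Gaussian window
#' (sigma 1.5), K1 = 0.01, K2 = 0.03, dynamic range taken from the declared
#' value range, computed over the valid (fully overlapping) window positions.
#' Color inputs are collapsed to luminance (Rec. 601 weights) first.
#'
#' @param a,b [ImageTensor-class] objects with identical shape and range; at
#'   least 11 x 11 pixels.
#' @return SSIM in \[-1, 1\]; 1 iff the images are identical.
#' @export
ssim <- function(a, b) {
  check_pair(a, b)
  d <- dim(a@pixels)
  if (d[1L] < 11L || d[2L] < 11L) {
    stop("images must be at least 11 x 11 for SSIM")
  }
  ga <- if (d[3L] == 3L) luminance(a@pixels) else a@pixels[, , 1L]
  gb <- if (d[3L] == 3L) luminance(b@pixels) else b@pixels[, , 1L]
  L <- a@valueRange[2L] - a@valueRange[1L]
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  w <- ssim_window()
  mu1 <- ssim_filter(ga, w)
  mu2 <- ssim_filter(gb, w)
  s11 <- ssim_filter(ga * ga, w) - mu1^2
  s22 <- ssim_filter(gb * gb, w) - mu2^2
  s12 <- ssim_filter(ga * gb, w) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Full image-quality report
#'
#' @param ref,test [ImageTensor-class] objects with identical shape and
#'   range.
#' @param maxValue peak value for PSNR (default: declared range top).
#' @return a [QualityReport-class] with MSE, PSNR (dB) and SSIM.
#' @export
qualityReport <- function(ref, test, maxValue = ref@valueRange[2L]) {
  new("QualityReport", mse = mse(ref, test),
      psnrDb = psnr(ref, test, maxValue), ssim = ssim(ref, test))
}
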