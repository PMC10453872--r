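# Internal helpers shared across modules.

clip_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# half-up rounding, fixed so quantization oracles are exact (round() in R is
# round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# derive a child seed from a base seed and an index, kept inside 32-bit range
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483646 + 1)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopifnot_image <- function(img) {
  if (!methods::is(img, "ImageTensor")) {
    stop("expected an ImageTensor", call. = FALSE)
  }
  methods::validObject(img)
  invisible(img)
}

same_geometry <- function(a, b) {
  identical(dim(a@pixels), dim(b@pixels)) &&
    isTRUE(all.equal(a@valueRange, b@valueRange))
}

# Rec. 601 luma, used to collapse RGB to a single channel for SSIM
luminance <- function(px) {
  0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
}

# sRGB [0,1] HxWx3 array -> CIELAB (D65), and back. grDevices::convertColor
# works on n x 3 matrices.
rgb_to_lab <- function(px) {
  d <- dim(px)
  lab <- grDevices::convertColor(matrix(px, ncol = 3L), from = "sRGB",
                                 to = "Lab")
  array(lab, d)
}

lab_to_rgb <- function(lab) {
  d <- dim(lab)
  px <- grDevices::convertColor(matrix(lab, ncol = 3L), from = "Lab",
                                to = "sRGB")
  array(px, d)
}

# mirror an out-of-range index back into 1..n (reflection without repeating
# the edge pixel; period 2(n-1))
reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  ifelse(j >= n, period - j, j) + 1L
}

# reflect-pad a matrix by p rows/cols on each side
reflect_pad <- function(m, p) {
  ri <- reflect_idx(seq.int(1L - p, nrow(m) + p), nrow(m))
  ci <- reflect_idx(seq.int(1L - p, ncol(m) + p), ncol(m))
  m[ri, ci, drop = FALSE]
}
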