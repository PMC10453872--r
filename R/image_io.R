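# PNG reading/writing on top of the built-in codec (src/png_io.cpp).

#' Read a PNG file as an ImageTensor
#'
#' Supports 8-bit non-interlaced gray, RGB and RGBA PNGs (an alpha channel is
#' dropped). Pixels are returned in \[0, 1\].
#'
#' @param path PNG file path.
#' @return an [ImageTensor-class].
#' @export
readPng <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  px <- .cpp_read_png(path.expand(path))
  if (dim(px)[3L] == 4L) px <- px[, , 1:3, drop = FALSE]
  ImageTensor(array(px / 255, dim(px)), c(0, 1),
              if (dim(px)[3L] == 1L) "GRAY" else "RGB")
}

#' Write an ImageTensor to a PNG file
#'
#' The image is quantized to 8 bits (half-up rounding) on its declared range.
#'
#' @param img an [ImageTensor-class] (RGB or GRAY).
#' @param path output path.
#' @export
writePng <- function(img, path) {
  stopifnot_image(img)
  if (img@colorSpace == "LAB") stop("convert LAB images to RGB before writing")
  scale <- 255 / (img@valueRange[2L] - img@valueRange[1L])
  q <- round_half_up((img@pixels - img@valueRange[1L]) * scale)
  q <- array(as.integer(clip_range(q, 0, 255)), dim(img@pixels))
  .cpp_write_png(path.expand(path), q)
  invisible(path)
}
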