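# Shared fixtures: tiny images and datasets built in code.

rand_image <- function(h, w, c = 3L, seed = 1L, range01 = TRUE) {
  withr::with_seed(seed, {
    px <- array(runif(h * w * c), c(h, w, c))
    ImageTensor(px, c(0, 1), if (c == 1L) "GRAY" else "RGB")
  })
}

gray_image <- function(values, range = c(0, 255)) {
  n <- length(values)
  side <- as.integer(sqrt(n))
  stopifnot(side * side == n)
  ImageTensor(matrix(values, side, side), range)
}

constant_image <- function(value, h = 16L, w = 16L, c = 3L, range = c(0, 1)) {
  ImageTensor(array(value, c(h, w, c)), range,
              if (c == 1L) "GRAY" else "RGB")
}

tiny_params <- function(...) {
  SyntheticParams(nImages = 12, imageSide = 24, seed = 99, ...)
}

# a small, strongly separable labeled image set for classifier tests
separable_batch <- function(n = 40L, side = 64L, seed = 5L) {
  p <- SyntheticParams(imageSide = side, seed = seed)
  cls <- rep(c("benign", "malignant"), length.out = n)
  imgs <- lapply(seq_len(n), function(i) {
    makeLesionImage(p, cls[i], seed = seed * 1000 + i)
  })
  list(images = imgs, targets = as.integer(cls == "malignant"),
       batch = imagesToBatch(imgs))
}

# direct 2-D convolution with reflect padding (oracle for blur-based ops)
conv2_reflect_oracle <- function(m, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  p <- lesiongan:::reflect_pad(m, r)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      patch <- p[i:(i + 2L * r), j:(j + 2L * r)]
      out[i, j] <- sum(patch * kernel)
    }
  }
  out
}
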