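# Dermoscopy preprocessing pipeline: normalization, bicubic rescaling,
# histogram equalization, combined USM + GHPF sharpening, CIELAB color
# balance, noise models, median filtering.

#' Normalize an 8-bit image to \[0, 1\]
#'
#' Divides pixel values by 255 and re-declares the range. Applying it to an
#' image already in \[0, 1\] is a no-op with a warning.
#'
#' @param img an [ImageTensor-class] with range \[0, 255\].
#' @return the image with range \[0, 1\].
#' @export
normalize01 <- function(img) {
  stopifnot_image(img)
  if (isTRUE(all.equal(img@valueRange, c(0, 1)))) {
    warning("image already in [0, 1]; returning unchanged")
    return(img)
  }
  ImageTensor(img@pixels / 255, c(0, 1), img@colorSpace)
}

# Keys cubic-convolution kernel, a = -0.5
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# out x in row-stochastic resampling matrix for one axis (pixel-center
# mapping, edge replication)
bicubic_matrix <- function(nIn, nOut) {
  M <- matrix(0, nOut, nIn)
  scale <- nIn / nOut
  for (o in seq_len(nOut)) {
    src <- (o - 0.5) * scale - 0.5        # 0-based source coordinate
    base <- floor(src)
    for (tap in -1:2) {
      j <- base + tap
      w <- cubic_kernel(src - j)
      jc <- min(max(j, 0), nIn - 1)       # replicate edges
      M[o, jc + 1] <- M[o, jc + 1] + w
    }
  }
  M
}

#' Rescale an image with bicubic interpolation
#'
#' Cubic-convolution resampling (Keys kernel, a = -0.5): every output pixel
#' is a weighted average of the 4 x 4 = 16 nearest source pixels, applied
#' separably and independently per channel, with edge replication and a final
#' clip to the declared range.
#'
#' @param img an [ImageTensor-class].
#' @param outH,outW output size in pixels (>= 1).
#' @return the resized image.
#' @export
resizeBicubic <- function(img, outH, outW) {
  stopifnot_image(img)
  d <- dim(img@pixels)
  if (any(d[1:2] < 1L) || length(img@pixels) == 0L) stop("empty image")
  if (outH < 1 || outW < 1) stop("output size must be at least 1x1")
  Mh <- bicubic_matrix(d[1L], as.integer(outH))
  Mw <- bicubic_matrix(d[2L], as.integer(outW))
  out <- array(0, c(as.integer(outH), as.integer(outW), d[3L]))
  for (c in seq_len(d[3L])) {
    out[, , c] <- Mh %*% img@pixels[, , c] %*% t(Mw)
  }
  out <- clip_range(out, img@valueRange[1L], img@valueRange[2L])
  ImageTensor(out, img@valueRange, img@colorSpace)
}

# quantize intensities to integer levels 0..255 on the declared range
quantize256 <- function(x, valueRange) {
  lev <- round_half_up((x - valueRange[1L]) * 255 /
                         (valueRange[2L] - valueRange[1L]))
  clip_range(lev, 0, 255)
}

#' Intensity histogram and CDF of an image
#'
#' Computes 256-bin counts of the quantized intensity and the cumulative
#' distribution function obtained by dividing the cumulative histogram by the
#' number of pixels. RGB input is collapsed to the CIELAB lightness channel
#' first; GRAY input uses its single channel directly.
#'
#' @param img an [ImageTensor-class].
#' @return a [HistogramCDF-class].
#' @examples
#' img <- ImageTensor(matrix(c(52, 52, 154, 200) / 255, 2, 2))
#' histogramCdf(img)@cdf[c(53, 155, 201)]  # cdf at levels 52, 154, 200
#' @export
histogramCdf <- function(img) {
  stopifnot_image(img)
  lev <- intensity_levels(img)
  counts <- tabulate(as.integer(lev) + 1L, nbins = 256L)
  new("HistogramCDF", binCounts = counts,
      cdf = cumsum(counts) / max(1L, length(lev)))
}

intensity_levels <- function(img) {
  if (img@colorSpace == "GRAY") {
    quantize256(img@pixels[, , 1L], img@valueRange)
  } else if (img@colorSpace == "RGB") {
    px <- (img@pixels - img@valueRange[1L]) /
      (img@valueRange[2L] - img@valueRange[1L])
    L <- rgb_to_lab(px)[, , 1L]
    clip_range(round_half_up(L / 100 * 255), 0, 255)
  } else {
    stop("histogram requires a GRAY or RGB image")
  }
}

# classical equalization map on quantized levels; returns the 256-entry
# lookup table, or NULL for a constant image
equalization_lut <- function(counts) {
  cdf <- cumsum(counts) / sum(counts)
  nz <- which(cdf > 0)
  cdfMin <- cdf[nz[1L]]
  if (1 - cdfMin <= 0) return(NULL)   # constant image: mapping is 0/0
  round_half_up((cdf - cdfMin) / (1 - cdfMin) * 255)
}

#' Histogram equalization
#'
#' Spreads the most common intensity values over the full range using the
#' classical CDF mapping `round((cdf(v) - cdf_min) / (1 - cdf_min) * 255)`
#' with half-up rounding. GRAY images are equalized directly on their
#' quantized channel; RGB images are equalized on the CIELAB lightness
#' channel with chroma preserved (avoiding hue distortion). A constant image
#' is returned unchanged (the mapping is 0/0 there).
#'
#' @param img an [ImageTensor-class] (GRAY or RGB).
#' @return the equalized image, same geometry and range.
#' @examples
#' img <- ImageTensor(matrix(c(52, 52, 154, 200), 2, 2), c(0, 255))
#' equalizeHistogram(img)@pixels[, , 1]  # 0, 0, 128, 255
#' @export
equalizeHistogram <- function(img) {
  stopifnot_image(img)
  vr <- img@valueRange
  if (img@colorSpace == "GRAY") {
    lev <- quantize256(img@pixels[, , 1L], vr)
    lut <- equalization_lut(tabulate(as.integer(lev) + 1L, nbins = 256L))
    if (is.null(lut)) return(img)
    out <- matrix(lut[as.integer(lev) + 1L], nrow(lev), ncol(lev))
    ImageTensor(array(out / 255 * (vr[2L] - vr[1L]) + vr[1L], dim(img@pixels)),
                vr, "GRAY")
  } else if (img@colorSpace == "RGB") {
    px <- (img@pixels - vr[1L]) / (vr[2L] - vr[1L])
    lab <- rgb_to_lab(px)
    lev <- clip_range(round_half_up(lab[, , 1L] / 100 * 255), 0, 255)
    lut <- equalization_lut(tabulate(as.integer(lev) + 1L, nbins = 256L))
    if (is.null(lut)) return(img)
    lab[, , 1L] <- matrix(lut[as.integer(lev) + 1L] / 255 * 100,
                          dim(px)[1L], dim(px)[2L])
    out <- clip_range(lab_to_rgb(lab), 0, 1)
    ImageTensor(out * (vr[2L] - vr[1L]) + vr[1L], vr, "RGB")
  } else {
    stop("equalization requires a GRAY or RGB image")
  }
}

# separable Gaussian blur with reflect padding; kernel truncated at 4 sigma
gaussian_blur_channel <- function(m, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  p <- reflect_pad(m, r)
  H <- nrow(m)
  W <- ncol(m)
  # rows
  tmp <- matrix(0, H, W + 2L * r)
  for (i in seq_along(k)) {
    tmp <- tmp + k[i] * p[seq_len(H) + i - 1L, , drop = FALSE]
  }
  out <- matrix(0, H, W)
  for (i in seq_along(k)) {
    out <- out + k[i] * tmp[, seq_len(W) + i - 1L, drop = FALSE]
  }
  out
}

#' Unsharp masking
#'
#' `out = clip(img + amount * (img - gaussian_blur(img, sigma)))`, per
#' channel, reflect padding, Gaussian kernel truncated at 4 sigma.
#'
#' @param img an [ImageTensor-class].
#' @param sigma blur scale in pixels (> 0).
#' @param amount mask gain (>= 0); 0 returns the input.
#' @return the sharpened image.
#' @export
sharpenUsm <- function(img, sigma = 1, amount = 1) {
  stopifnot_image(img)
  if (sigma <= 0) stop("sigma must be positive")
  if (amount < 0) stop("amount must be nonnegative")
  out <- img@pixels
  for (c in seq_len(dim(out)[3L])) {
    blur <- gaussian_blur_channel(img@pixels[, , c], sigma)
    out[, , c] <- img@pixels[, , c] + amount * (img@pixels[, , c] - blur)
  }
  ImageTensor(clip_range(out, img@valueRange[1L], img@valueRange[2L]),
              img@valueRange, img@colorSpace)
}

# frequency grid in cycles/pixel for an FFT of length n
fft_freqs <- function(n) {
  c(seq.int(0L, floor(n / 2)), seq.int(-(ceiling(n / 2) - 1L), -1L)) / n
}

#' Gaussian high-pass sharpening
#'
#' Frequency-domain filtering with the Gaussian high-pass transfer
#' `H(u, v) = 1 - exp(-D(u, v)^2 / (2 cutoff^2))` where `D` is the distance
#' from the zero frequency in cycles/pixel (Nyquist = 0.5);
#' `out = clip(img + gain * highpass(img))` per channel. The DC component is
#' exactly rejected, so constants pass through unchanged.
#'
#' @param img an [ImageTensor-class].
#' @param cutoff Gaussian cutoff D0 in cycles/pixel (> 0); default 0.05
#'   (one tenth of Nyquist).
#' @param gain high-pass gain (>= 0); 0 returns the input.
#' @return the sharpened image.
#' @export
ghpf <- function(img, cutoff = 0.05, gain = 1) {
  stopifnot_image(img)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (gain < 0) stop("gain must be nonnegative")
  d <- dim(img@pixels)
  fu <- fft_freqs(d[1L])
  fv <- fft_freqs(d[2L])
  D2 <- outer(fu^2, fv^2, "+")
  H <- 1 - exp(-D2 / (2 * cutoff^2))
  out <- img@pixels
  for (c in seq_len(d[3L])) {
    F <- fft(img@pixels[, , c])
    hp <- Re(fft(F * H, inverse = TRUE)) / (d[1L] * d[2L])
    out[, , c] <- img@pixels[, , c] + gain * hp
  }
  ImageTensor(clip_range(out, img@valueRange[1L], img@valueRange[2L]),
              img@valueRange, img@colorSpace)
}

#' Combined USM + GHPF sharpening
#'
#' The two sharpened branches are blended:
#' `out = clip(weightUsm * sharpenUsm(img) + weightGhpf * ghpf(img))`. With
#' weights (1, 0) or (0, 1) this reduces to the single branch.
#'
#' @param img an [ImageTensor-class].
#' @param cfg a [SharpenConfig-class]; defaults per `SharpenConfig()`.
#' @return the sharpened image.
#' @export
combineSharpen <- function(img, cfg = SharpenConfig()) {
  stopifnot_image(img)
  methods::validObject(cfg)
  u <- sharpenUsm(img, cfg@usmSigma, cfg@usmAmount)
  g <- ghpf(img, cfg@ghpfCutoff, cfg@ghpfGain)
  out <- cfg@weightUsm * u@pixels + cfg@weightGhpf * g@pixels
  ImageTensor(clip_range(out, img@valueRange[1L], img@valueRange[2L]),
              img@valueRange, img@colorSpace)
}

#' CIELAB color balance
#'
#' Converts to CIELAB and standardizes each channel to target statistics:
#' `out_c = (c - mean(c)) * targetStds[c] / sd(c) + targetMeans[c]`, then
#' converts back to sRGB and clips. A zero-variance channel keeps scale
#' factor 1 (only its mean is moved). Default targets (L 50, a 0, b 0;
#' spreads 25, 10, 10) center the image on neutral mid-lightness; they are
#' package defaults, not published values.
#'
#' @param img an RGB [ImageTensor-class].
#' @param targetMeans,targetStds numeric(3) CIELAB channel targets.
#' @return the color-balanced RGB image.
#' @export
colorBalanceLab <- function(img, targetMeans = c(50, 0, 0),
                            targetStds = c(25, 10, 10)) {
  stopifnot_image(img)
  if (img@colorSpace != "RGB") stop("color balance requires an RGB image")
  if (any(targetStds <= 0)) stop("targetStds must be positive")
  vr <- img@valueRange
  px <- (img@pixels - vr[1L]) / (vr[2L] - vr[1L])
  lab <- rgb_to_lab(px)
  for (c in 1:3) {
    ch <- lab[, , c]
    m <- mean(ch)
    s <- sd(as.vector(ch))
    fac <- if (is.na(s) || s < 1e-12) 1 else targetStds[c] / s
    lab[, , c] <- (ch - m) * fac + targetMeans[c]
  }
  out <- clip_range(lab_to_rgb(lab), 0, 1)
  ImageTensor(out * (vr[2L] - vr[1L]) + vr[1L], vr, "RGB")
}

#' Corrupt an image with a seeded noise model
#'
#' Salt-and-pepper sets a fraction `density` of pixel locations (all
#' channels) to the range minimum or maximum equiprobably; Gaussian adds
#' `N(0, sigma^2)` scaled to the declared range; speckle multiplies by
#' `1 + N(0, sigma^2)`; Poisson resamples intensities scaled to the photon
#' budget. Output is clipped. Identical specs corrupt identically.
#'
#' @param img an [ImageTensor-class].
#' @param spec a [NoiseSpec-class].
#' @return the corrupted image.
#' @export
addNoise <- function(img, spec) {
  stopifnot_image(img)
  methods::validObject(spec)
  vr <- img@valueRange
  span <- vr[2L] - vr[1L]
  d <- dim(img@pixels)
  out <- with_seed(spec@seed, {
    px <- img@pixels
    switch(spec@kind,
      salt_pepper = {
        if (spec@density > 0) {
          npix <- d[1L] * d[2L]
          hit <- which(runif(npix) < spec@density)
          if (length(hit) > 0L) {
            val <- ifelse(runif(length(hit)) < 0.5, vr[1L], vr[2L])
            for (c in seq_len(d[3L])) {
              ch <- px[, , c]
              ch[hit] <- val
              px[, , c] <- ch
            }
          }
        }
        px
      },
      gaussian = px + if (spec@sigma > 0) {
        array(rnorm(length(px), 0, spec@sigma * span), d)
      } else 0,
      speckle = px * (1 + if (spec@sigma > 0) {
        array(rnorm(length(px), 0, spec@sigma), d)
      } else 0),
      poisson = {
        lam <- clip_range((px - vr[1L]) / span, 0, 1) * spec@photons
        array(rpois(length(px), lam) / spec@photons * span + vr[1L], d)
      })
  })
  ImageTensor(clip_range(out, vr[1L], vr[2L]), vr, img@colorSpace)
}

#' Median filter
#'
#' Per-channel k x k sliding-window median with reflect padding; removes
#' impulse noise (and softens fine hair streaks) while preserving edges.
#'
#' @param img an [ImageTensor-class].
#' @param k odd window size >= 3.
#' @return the filtered image.
#' @export
medianFilter <- function(img, k = 3L) {
  stopifnot_image(img)
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stop("k must be an odd integer >= 3")
  p <- (k - 1L) %/% 2L
  d <- dim(img@pixels)
  out <- img@pixels
  for (c in seq_len(d[3L])) {
    pad <- reflect_pad(img@pixels[, , c], p)
    stack <- matrix(0, d[1L] * d[2L], k * k)
    col <- 1L
    for (dw in 0:(k - 1L)) {
      for (dh in 0:(k - 1L)) {
        stack[, col] <- pad[seq_len(d[1L]) + dh, seq_len(d[2L]) + dw]
        col <- col + 1L
      }
    }
    out[, , c] <- matrix(apply(stack, 1L, median), d[1L], d[2L])
  }
  ImageTensor(out, img@valueRange, img@colorSpace)
}

#' Pipeline configuration
#'
#' @param outSize target square size for bicubic rescaling (default 64, the
#'   network input size).
#' @param normalize,equalize,sharpen,colorBalance,medianFilter logical stage
#'   toggles.
#' @param sharpenConfig a [SharpenConfig-class].
#' @param labTargetMeans,labTargetStds CIELAB color-balance targets.
#' @param medianK median window size.
#' @return a named list understood by [preprocessPipeline()].
#' @export
preprocessConfig <- function(outSize = 64, normalize = TRUE, equalize = TRUE,
                             sharpen = TRUE, colorBalance = TRUE,
                             medianFilter = TRUE,
                             sharpenConfig = SharpenConfig(),
                             labTargetMeans = c(50, 0, 0),
                             labTargetStds = c(25, 10, 10), medianK = 3L) {
  list(outSize = outSize, normalize = normalize, equalize = equalize,
       sharpen = sharpen, colorBalance = colorBalance,
       medianFilter = medianFilter, sharpenConfig = sharpenConfig,
       labTargetMeans = labTargetMeans, labTargetStds = labTargetStds,
       medianK = medianK)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: bicubic rescaling, normalization to \[0, 1\], histogram
#' equalization, combined USM + GHPF sharpening, CIELAB color balance, and
#' median filtering. Every stage after rescaling can be toggled off in the
#' configuration; with all stages disabled this is resize-only.
#'
#' @param img an RGB [ImageTensor-class].
#' @param cfg configuration list from [preprocessConfig()].
#' @return the preprocessed image (size `outSize`, range \[0, 1\] when
#'   normalization is on).
#' @export
preprocessPipeline <- function(img, cfg = preprocessConfig()) {
  stopifnot_image(img)
  if (img@colorSpace != "RGB") stop("pipeline expects an RGB image")
  out <- resizeBicubic(img, cfg$outSize, cfg$outSize)
  if (isTRUE(cfg$normalize) && !isTRUE(all.equal(out@valueRange, c(0, 1)))) {
    out <- normalize01(out)
  }
  if (isTRUE(cfg$equalize)) out <- equalizeHistogram(out)
  if (isTRUE(cfg$sharpen)) out <- combineSharpen(out, cfg$sharpenConfig)
  if (isTRUE(cfg$colorBalance)) {
    out <- colorBalanceLab(out, cfg$labTargetMeans, cfg$labTargetStds)
  }
  if (isTRUE(cfg$medianFilter)) out <- medianFilter(out, cfg$medianK)
  out
}
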