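# Preprocessing pipeline: each operation against an independent oracle.

test_that("normalize01 rescales 8-bit images and warns on no-ops", {
  img <- gray_image(c(0, 128, 255, 64))
  out <- normalize01(img)
  expect_equal(out@valueRange, c(0, 1))
  expect_equal(as.vector(out@pixels), c(0, 128, 255, 64) / 255)
  expect_equal(out@pixels[2], 128 / 255, tolerance = 1e-12)
  expect_warning(again <- normalize01(out), "already")
  expect_equal(again@pixels, out@pixels)
  # endpoints
  expect_equal(max(normalize01(gray_image(rep(255, 4)))@pixels), 1)
  expect_equal(min(normalize01(gray_image(rep(0, 4)))@pixels), 0)
})

# independent bicubic oracle: direct 2-D Keys-kernel summation over all taps
bicubic_oracle <- function(px, outH, outW) {
  keys <- function(t, a = -0.5) {
    t <- abs(t)
    if (t <= 1) (a + 2) * t^3 - (a + 3) * t^2 + 1
    else if (t < 2) a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a
    else 0
  }
  H <- nrow(px)
  W <- ncol(px)
  out <- matrix(0, outH, outW)
  for (oh in seq_len(outH)) {
    for (ow in seq_len(outW)) {
      sy <- (oh - 0.5) * H / outH - 0.5
      sx <- (ow - 0.5) * W / outW - 0.5
      acc <- 0
      for (ty in floor(sy) + (-1:2)) {
        for (tx in floor(sx) + (-1:2)) {
          w <- keys(sy - ty) * keys(sx - tx)
          yy <- min(max(ty, 0), H - 1)
          xx <- min(max(tx, 0), W - 1)
          acc <- acc + w * px[yy + 1, xx + 1]
        }
      }
      out[oh, ow] <- acc
    }
  }
  out
}

test_that("bicubic resize reproduces constants, identity, and the kernel oracle", {
  const <- constant_image(0.5, 8, 8)
  up <- resizeBicubic(const, 13, 11)
  expect_equal(dim(up), c(13L, 11L, 3L))
  expect_true(all(abs(up@pixels - 0.5) < 1e-12))

  img <- rand_image(7, 7, 3, seed = 2)
  same <- resizeBicubic(img, 7, 7)
  expect_lt(max(abs(same@pixels - img@pixels)), 1e-9)

  src <- rand_image(6, 6, 1, seed = 3)
  out <- resizeBicubic(src, 9, 9)
  oracle <- bicubic_oracle(src@pixels[, , 1], 9, 9)
  # clip as the operation does
  expect_lt(max(abs(out@pixels[, , 1] - pmin(pmax(oracle, 0), 1))), 1e-6)

  expect_error(resizeBicubic(img, 0, 5), "at least")
})

test_that("an interior non-grid output pixel depends on exactly 16 source pixels", {
  base <- rand_image(8, 8, 1, seed = 4)
  # output pixel (5,5) of an 8 -> 11 upscale sits at a non-integer source
  # position well inside the image
  ref <- resizeBicubic(base, 11, 11)@pixels[5, 5, 1]
  influential <- 0L
  for (i in 1:8) {
    for (j in 1:8) {
      px <- base@pixels
      px[i, j, 1] <- px[i, j, 1] + 1e-4
      pert <- resizeBicubic(ImageTensor(px), 11, 11)@pixels[5, 5, 1]
      if (abs(pert - ref) > 1e-12) influential <- influential + 1L
    }
  }
  expect_identical(influential, 16L)
})

test_that("histogramCdf counts and normalizes correctly", {
  img <- gray_image(c(52, 52, 154, 200))
  h <- histogramCdf(img)
  expect_equal(sum(h@binCounts), 4)
  expect_equal(h@cdf[52 + 1], 0.5)
  expect_equal(h@cdf[154 + 1], 0.75)
  expect_equal(h@cdf[200 + 1], 1.0)
  expect_equal(h@cdf[256], 1.0)

  const <- histogramCdf(gray_image(rep(77, 9)))
  expect_equal(sum(const@binCounts > 0), 1)
  expect_equal(const@cdf[77], 0)       # level 76
  expect_equal(const@cdf[78], 1)       # level 77: cdf jumps 0 -> 1
  # any non-empty image ends at 1
  expect_equal(histogramCdf(rand_image(5, 5, 1, seed = 8))@cdf[256], 1)
})

test_that("histogram equalization matches the CDF-mapping oracle", {
  img <- gray_image(c(52, 52, 154, 200))
  out <- equalizeHistogram(img)
  expect_equal(sort(as.vector(out@pixels)), c(0, 0, 128, 255))

  # 50/50 two-level image at the extremes is a fixed point
  bi <- gray_image(c(0, 0, 255, 255))
  expect_equal(equalizeHistogram(bi)@pixels, bi@pixels)

  # constant image returned unchanged (degenerate 0/0 mapping)
  const <- gray_image(rep(130, 16))
  expect_equal(equalizeHistogram(const)@pixels, const@pixels)
})

test_that("equalization moves a 2-mode luminance CDF toward uniform", {
  # Kolmogorov-Smirnov distance to the uniform CDF must not increase
  withr::with_seed(10, {
    v <- c(round(rnorm(128, 60, 6)), round(rnorm(128, 90, 6)))
  })
  img <- gray_image(pmin(pmax(v, 0), 255))
  ks_uniform <- function(im) {
    cdf <- histogramCdf(im)@cdf
    max(abs(cdf - (0:255) / 255))
  }
  expect_lte(ks_uniform(equalizeHistogram(img)), ks_uniform(img))
})

test_that("unsharp masking matches a direct convolution oracle", {
  img <- rand_image(9, 9, 1, seed = 6)
  expect_equal(sharpenUsm(img, 1, 0)@pixels, img@pixels)
  const <- constant_image(0.4, 10, 10, 1)
  expect_equal(sharpenUsm(const, 1.5, 2)@pixels, const@pixels)

  # 1-D step edge: overshoot equals img + amount * (img - blur) with the
  # blur recomputed by brute-force 2-D convolution of the same kernel
  step <- ImageTensor(matrix(rep(c(0.2, 0.2, 0.2, 0.8, 0.8, 0.8), each = 6),
                             6, 6))
  sigma <- 1
  r <- ceiling(4 * sigma)
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  blur <- conv2_reflect_oracle(step@pixels[, , 1], outer(k1, k1))
  oracle <- pmin(pmax(step@pixels[, , 1] +
                        1 * (step@pixels[, , 1] - blur), 0), 1)
  out <- sharpenUsm(step, sigma, 1)
  expect_lt(max(abs(out@pixels[, , 1] - oracle)), 1e-6)
})

test_that("GHPF rejects DC and attenuates a single cosine by the transfer value", {
  const <- constant_image(0.37, 12, 12, 1)
  out <- ghpf(const, 0.1, 1)
  expect_lt(max(abs(out@pixels - 0.37)), 1e-9)

  img <- rand_image(8, 8, 1, seed = 7)
  expect_equal(ghpf(img, 0.1, 0)@pixels, img@pixels)

  # cosine of known frequency: output = img + gain * H(f) * cosine component
  H <- 32
  kcyc <- 5
  f <- kcyc / H
  cutoff <- 0.08
  gain <- 0.5
  cosine <- matrix(rep(0.25 * cos(2 * pi * kcyc * (0:(H - 1)) / H), times = H),
                   H, H)
  img <- ImageTensor(matrix(0.5, H, H) + cosine)
  hf <- 1 - exp(-f^2 / (2 * cutoff^2))
  expected <- 0.5 + (1 + gain * hf) * cosine
  out <- ghpf(img, cutoff, gain)
  expect_lt(max(abs(out@pixels[, , 1] - expected)), 1e-6)
})

test_that("combined sharpening blends the two branches", {
  img <- rand_image(10, 10, 3, seed = 9)
  usmOnly <- combineSharpen(img, SharpenConfig(weightUsm = 1, weightGhpf = 0))
  expect_equal(usmOnly@pixels, sharpenUsm(img, 1, 1)@pixels)

  const <- constant_image(0.6, 12, 12)
  half <- combineSharpen(const,
                         SharpenConfig(weightUsm = 0.5, weightGhpf = 0.5))
  expect_lt(max(abs(half@pixels - 0.6)), 1e-9)

  # equals the pixelwise mean of the branch outputs (before the final clip,
  # which is inactive for interior values here)
  cfg <- SharpenConfig(weightUsm = 0.5, weightGhpf = 0.5,
                       usmAmount = 0.3, ghpfGain = 0.3)
  mean2 <- 0.5 * sharpenUsm(img, cfg@usmSigma, cfg@usmAmount)@pixels +
    0.5 * ghpf(img, cfg@ghpfCutoff, cfg@ghpfGain)@pixels
  got <- combineSharpen(img, cfg)
  expect_lt(max(abs(got@pixels - pmin(pmax(mean2, 0), 1))), 1e-12)

  expect_error(SharpenConfig(weightUsm = 0, weightGhpf = 0), "positive")
})

test_that("CIELAB color balance hits its channel targets", {
  img <- rand_image(16, 16, 3, seed = 12)
  lab <- lesiongan:::rgb_to_lab(img@pixels)
  means <- apply(lab, 3, mean)
  sds <- apply(lab, 3, function(ch) sd(as.vector(ch)))

  # image whose stats already equal the targets is a fixed point up to the
  # color round trip
  fixed <- colorBalanceLab(img, targetMeans = means, targetStds = sds)
  expect_lt(max(abs(fixed@pixels - img@pixels)), 2 / 255)

  # moderate in-gamut targets are matched within 0.5 LAB units
  out <- colorBalanceLab(img, targetMeans = c(55, 3, 3),
                         targetStds = c(12, 4, 4))
  outLab <- lesiongan:::rgb_to_lab(out@pixels)
  expect_lt(max(abs(apply(outLab, 3, mean) - c(55, 3, 3))), 0.5)
  expect_true(all(out@pixels >= 0 & out@pixels <= 1))

  # zero-variance channel: scale factor 1, mean still moved
  flat <- constant_image(0.5, 8, 8)
  shifted <- colorBalanceLab(flat, targetMeans = c(60, 0, 0),
                             targetStds = c(10, 5, 5))
  expect_true(all(is.finite(shifted@pixels)))
})

test_that("noise models corrupt as specified and are seeded", {
  img <- constant_image(0.5, 100, 100, 1)
  expect_equal(addNoise(img, NoiseSpec("salt_pepper", density = 0))@pixels,
               img@pixels)
  expect_equal(addNoise(img, NoiseSpec("gaussian", sigma = 0))@pixels,
               img@pixels)

  sp <- addNoise(img, NoiseSpec("salt_pepper", density = 0.1, seed = 21))
  frac <- mean(sp@pixels != 0.5)
  se <- sqrt(0.1 * 0.9 / 1e4)
  expect_lt(abs(frac - 0.1), 3 * se)
  # corrupted pixels sit at the range endpoints
  expect_true(all(sp@pixels %in% c(0, 0.5, 1)))

  # identical specs corrupt identically; different seeds differ
  sp2 <- addNoise(img, NoiseSpec("salt_pepper", density = 0.1, seed = 21))
  expect_identical(sp@pixels, sp2@pixels)
  sp3 <- addNoise(img, NoiseSpec("salt_pepper", density = 0.1, seed = 22))
  expect_false(identical(sp@pixels, sp3@pixels))

  pois <- addNoise(img, NoiseSpec("poisson", seed = 5))
  expect_true(all(pois@pixels >= 0 & pois@pixels <= 1))
  spk <- addNoise(img, NoiseSpec("speckle", sigma = 0.2, seed = 6))
  expect_true(all(spk@pixels >= 0 & spk@pixels <= 1))
})

test_that("median filter matches the sorting oracle and removes impulses", {
  img <- ImageTensor(matrix(1:9 / 9, 3, 3))
  expect_equal(medianFilter(img, 3)@pixels[2, 2, 1], 5 / 9)

  const <- constant_image(0.3, 9, 9, 1)
  px <- const@pixels
  px[5, 5, 1] <- 1
  cleaned <- medianFilter(ImageTensor(px), 3)
  expect_true(all(abs(cleaned@pixels - 0.3) < 1e-12))

  rnd <- rand_image(8, 8, 1, seed = 30)
  out <- medianFilter(rnd, 3)
  pad <- lesiongan:::reflect_pad(rnd@pixels[, , 1], 1L)
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) {
    for (j in 1:8) {
      win <- sort(as.vector(pad[i:(i + 2), j:(j + 2)]))
      oracle[i, j] <- win[5]   # middle of 9
    }
  }
  expect_identical(out@pixels[, , 1], oracle)

  expect_error(medianFilter(rnd, 4), "odd")

  # idempotent on impulse-noise fixtures
  noisy <- addNoise(constant_image(0.5, 12, 12, 1),
                    NoiseSpec("salt_pepper", density = 0.05, seed = 3))
  once <- medianFilter(noisy, 3)
  expect_equal(medianFilter(once, 3)@pixels, once@pixels)
})

test_that("the pipeline composes its stages in order", {
  img <- rand_image(20, 24, 3, seed = 40)
  offCfg <- preprocessConfig(outSize = 16, equalize = FALSE, sharpen = FALSE,
                             colorBalance = FALSE, medianFilter = FALSE)
  expect_equal(preprocessPipeline(img, offCfg)@pixels,
               resizeBicubic(img, 16, 16)@pixels)

  cfg <- preprocessConfig(outSize = 16)
  out <- preprocessPipeline(img, cfg)
  expect_equal(dim(out), c(16L, 16L, 3L))
  expect_true(all(out@pixels >= 0 & out@pixels <= 1))

  manual <- resizeBicubic(img, 16, 16)
  manual <- equalizeHistogram(manual)
  manual <- combineSharpen(manual, cfg$sharpenConfig)
  manual <- colorBalanceLab(manual, cfg$labTargetMeans, cfg$labTargetStds)
  manual <- medianFilter(manual, cfg$medianK)
  expect_equal(out@pixels, manual@pixels)
})

test_that("operations preserve shape and declared range", {
  img <- rand_image(12, 14, 3, seed = 50)
  ops <- list(
    function(x) equalizeHistogram(x),
    function(x) sharpenUsm(x, 1, 2),
    function(x) ghpf(x, 0.05, 2),
    function(x) combineSharpen(x),
    function(x) colorBalanceLab(x),
    function(x) addNoise(x, NoiseSpec("gaussian", sigma = 0.2, seed = 1)),
    function(x) medianFilter(x, 3))
  for (op in ops) {
    out <- op(img)
    expect_identical(dim(out), dim(img))
    expect_true(all(out@pixels >= -1e-9 & out@pixels <= 1 + 1e-9))
  }
})
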