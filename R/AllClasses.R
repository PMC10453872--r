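#' @useDynLib lesiongan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif rpois median sd fft
#' @importFrom utils read.csv write.csv
NULL

VALUE_RANGE_TOL <- 1e-8

#' ImageTensor: an image with a declared intensity range
#'
#' The central image container: an H x W x C array of real intensities, a
#' declared value range (`c(0, 1)` or `c(0, 255)`) and a color space tag
#' (`"RGB"`, `"LAB"` or `"GRAY"`). Every preprocessing operation consumes and
#' returns this class and clipping stages guarantee pixels stay inside the
#' declared range. For `"LAB"` images the range describes the RGB image the
#' values originated from; LAB channel values are not range-checked.
#'
#' @slot pixels numeric H x W x C array.
#' @slot valueRange numeric(2), the declared intensity range.
#' @slot colorSpace character, one of `"RGB"`, `"LAB"`, `"GRAY"`.
#' @export
setClass("ImageTensor",
  slots = c(pixels = "array", valueRange = "numeric", colorSpace = "character"))

setValidity("ImageTensor", function(object) {
  px <- object@pixels
  if (length(dim(px)) != 3L) return("pixels must be an H x W x C array")
  cs <- object@colorSpace
  if (!cs %in% c("RGB", "LAB", "GRAY")) {
    return("colorSpace must be one of 'RGB', 'LAB', 'GRAY'")
  }
  nc <- dim(px)[3L]
  if (cs == "GRAY" && nc != 1L) return("GRAY images must have 1 channel")
  if (cs != "GRAY" && nc != 3L) return("RGB/LAB images must have 3 channels")
  vr <- object@valueRange
  if (length(vr) != 2L || vr[1L] >= vr[2L]) {
    return("valueRange must be c(low, high) with low < high")
  }
  if (cs != "LAB" && length(px) > 0L) {
    rng <- range(px)
    if (rng[1L] < vr[1L] - VALUE_RANGE_TOL || rng[2L] > vr[2L] + VALUE_RANGE_TOL) {
      return(sprintf("pixel values [%g, %g] outside declared range [%g, %g]",
                     rng[1L], rng[2L], vr[1L], vr[2L]))
    }
  }
  TRUE
})

#' Construct an ImageTensor
#'
#' @param pixels numeric H x W x C array (a matrix is promoted to H x W x 1).
#' @param valueRange numeric(2) declared intensity range; default `c(0, 1)`.
#' @param colorSpace `"RGB"`, `"LAB"` or `"GRAY"`; default guessed from the
#'   channel count (3 -> RGB, 1 -> GRAY).
#' @return an [ImageTensor-class] object.
#' @examples
#' img <- ImageTensor(array(0.5, c(8, 8, 3)))
#' dim(img)
#' @export
ImageTensor <- function(pixels, valueRange = c(0, 1), colorSpace = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (is.null(colorSpace)) {
    colorSpace <- if (dim(pixels)[3L] == 1L) "GRAY" else "RGB"
  }
  new("ImageTensor", pixels = pixels, valueRange = as.numeric(valueRange),
      colorSpace = colorSpace)
}

#' @describeIn ImageTensor-class image dimensions (H, W, C)
#' @param x an `ImageTensor`
#' @export
setMethod("dim", "ImageTensor", function(x) dim(x@pixels))

setMethod("show", "ImageTensor", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageTensor %dx%dx%d %s, range [%g, %g]\n",
              d[1L], d[2L], d[3L], object@colorSpace,
              object@valueRange[1L], object@valueRange[2L]))
})

#' Intensity histogram and cumulative distribution of an image
#'
#' 256-bin intensity counts plus the normalized cumulative distribution
#' function obtained by dividing the cumulative histogram by the pixel count.
#'
#' @slot binCounts integer(256) counts for intensity levels 0..255.
#' @slot cdf numeric(256) nondecreasing, ending at 1 for non-empty images.
#' @export
setClass("HistogramCDF", slots = c(binCounts = "integer", cdf = "numeric"))

setValidity("HistogramCDF", function(object) {
  if (length(object@binCounts) != 256L) return("binCounts must have 256 bins")
  if (length(object@cdf) != 256L) return("cdf must have 256 values")
  if (any(object@binCounts < 0L)) return("binCounts must be nonnegative")
  if (any(diff(object@cdf) < -1e-12)) return("cdf must be nondecreasing")
  TRUE
})

setMethod("show", "HistogramCDF", function(object) {
  cat(sprintf("HistogramCDF: %d pixels, %d occupied bins\n",
              sum(object@binCounts), sum(object@binCounts > 0L)))
})

#' Configuration for the combined USM + GHPF sharpening stage
#'
#' Unsharp masking operates in the spatial domain (Gaussian blur of scale
#' `usmSigma`, mask gain `usmAmount`); the Gaussian high-pass filter operates
#' in the frequency domain with cutoff `ghpfCutoff` (cycles/pixel; Nyquist is
#' 0.5) and gain `ghpfGain`. The two sharpened branches are blended with
#' weights `weightUsm` and `weightGhpf`, at least one of which must be
#' positive.
#'
#' @slot usmSigma,usmAmount,ghpfCutoff,ghpfGain,weightUsm,weightGhpf numeric
#'   scalars; see Description.
#' @export
setClass("SharpenConfig",
  slots = c(usmSigma = "numeric", usmAmount = "numeric", ghpfCutoff = "numeric",
            ghpfGain = "numeric", weightUsm = "numeric", weightGhpf = "numeric"))

setValidity("SharpenConfig", function(object) {
  if (object@usmSigma <= 0) return("usmSigma must be positive")
  if (object@usmAmount < 0) return("usmAmount must be nonnegative")
  if (object@ghpfCutoff <= 0) return("ghpfCutoff must be positive")
  if (object@ghpfGain < 0) return("ghpfGain must be nonnegative")
  if (object@weightUsm < 0 || object@weightGhpf < 0) {
    return("weights must be nonnegative")
  }
  if (object@weightUsm + object@weightGhpf <= 0) {
    return("weightUsm + weightGhpf must be positive")
  }
  TRUE
})

#' @rdname SharpenConfig-class
#' @param usmSigma Gaussian blur scale of the unsharp mask (pixels).
#' @param usmAmount unsharp mask gain.
#' @param ghpfCutoff Gaussian high-pass cutoff D0 in cycles/pixel
#'   (default 0.05 = 0.1 x Nyquist).
#' @param ghpfGain high-pass gain.
#' @param weightUsm,weightGhpf blend weights for the two branches.
#' @export
SharpenConfig <- function(usmSigma = 1, usmAmount = 1, ghpfCutoff = 0.05,
                          ghpfGain = 1, weightUsm = 0.5, weightGhpf = 0.5) {
  new("SharpenConfig", usmSigma = usmSigma, usmAmount = usmAmount,
      ghpfCutoff = ghpfCutoff, ghpfGain = ghpfGain, weightUsm = weightUsm,
      weightGhpf = weightGhpf)
}

#' Specification of a stochastic image corruption
#'
#' @slot kind one of `"salt_pepper"`, `"poisson"`, `"speckle"`, `"gaussian"`.
#' @slot density fraction of corrupted pixels (salt-and-pepper only).
#' @slot sigma noise scale (gaussian/speckle), on the image's intensity scale
#'   relative to its declared range.
#' @slot photons Poisson photon budget used to scale intensities before
#'   resampling (default 255).
#' @slot seed integer RNG seed; identical specs corrupt identically.
#' @export
setClass("NoiseSpec",
  slots = c(kind = "character", density = "numeric", sigma = "numeric",
            photons = "numeric", seed = "numeric"))

setValidity("NoiseSpec", function(object) {
  if (!object@kind %in% c("salt_pepper", "poisson", "speckle", "gaussian")) {
    return("kind must be salt_pepper, poisson, speckle or gaussian")
  }
  if (object@density < 0 || object@density > 1) {
    return("density must lie in [0, 1]")
  }
  if (object@sigma < 0) return("sigma must be nonnegative")
  if (object@photons <= 0) return("photons must be positive")
  TRUE
})

#' @rdname NoiseSpec-class
#' @param kind,density,sigma,photons,seed see the corresponding slots.
#' @export
NoiseSpec <- function(kind, density = 0, sigma = 0, photons = 255, seed = 1L) {
  new("NoiseSpec", kind = kind, density = density, sigma = sigma,
      photons = photons, seed = as.numeric(seed))
}

#' Parameters of the synthetic two-class lesion dataset generator
#'
#' The generator emulates an ISIC-style archive: skin-toned backgrounds, one
#' elliptical lesion blob per image whose border irregularity and color
#' dispersion depend on the class, optional hair-like streaks, and a metadata
#' CSV with the eight standard fields. Class signal is carried by border
#' irregularity and color statistics so that a trivial mean-color threshold
#' separates the default classes (downstream classifier tests stay
#' well-posed). Identical parameters (including the seed) produce
#' byte-identical datasets.
#'
#' @slot nImages total number of images.
#' @slot classBalance malignant fraction in (0, 1).
#' @slot imageSide square image side in pixels (>= 16).
#' @slot lesionIrregularity named numeric(2) (`benign`, `malignant`) border
#'   jaggedness; 0 is a smooth ellipse.
#' @slot colorMeans 2 x 3 matrix (rows `benign`, `malignant`) of mean lesion
#'   RGB in \[0, 1\].
#' @slot colorSpreads 2 x 3 matrix of per-channel lesion color dispersion.
#' @slot hairProbability probability that an image receives hair streaks.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticParams",
  slots = c(nImages = "numeric", classBalance = "numeric",
            imageSide = "numeric", lesionIrregularity = "numeric",
            colorMeans = "matrix", colorSpreads = "matrix",
            hairProbability = "numeric", seed = "numeric"))

setValidity("SyntheticParams", function(object) {
  if (object@nImages < 1) return("nImages must be positive")
  if (object@classBalance <= 0 || object@classBalance >= 1) {
    return("classBalance must lie in (0, 1)")
  }
  if (object@imageSide < 16) return("imageSide must be at least 16")
  if (!all(c("benign", "malignant") %in% names(object@lesionIrregularity))) {
    return("lesionIrregularity needs 'benign' and 'malignant' entries")
  }
  if (any(object@lesionIrregularity < 0)) {
    return("lesionIrregularity must be nonnegative")
  }
  for (m in c("colorMeans", "colorSpreads")) {
    mm <- slot(object, m)
    if (!all(dim(mm) == c(2L, 3L)) ||
        !all(rownames(mm) == c("benign", "malignant"))) {
      return(sprintf("%s must be a 2x3 matrix with rows benign, malignant", m))
    }
  }
  if (object@hairProbability < 0 || object@hairProbability > 1) {
    return("hairProbability must lie in [0, 1]")
  }
  TRUE
})

#' @rdname SyntheticParams-class
#' @param nImages,classBalance,imageSide,hairProbability,seed see slots.
#' @param lesionIrregularity named numeric(2); defaults: benign lesions are
#'   near-elliptical (0.06), malignant borders are jagged (0.25).
#' @param colorMeans,colorSpreads 2 x 3 matrices (rows benign, malignant);
#'   defaults give benign lesions a light tan and malignant lesions a dark,
#'   strongly variegated brown.
#' @export
SyntheticParams <- function(nImages = 2000, classBalance = 0.5, imageSide = 64,
                            lesionIrregularity = c(benign = 0.06,
                                                   malignant = 0.25),
                            colorMeans = NULL, colorSpreads = NULL,
                            hairProbability = 0.2, seed = 1L) {
  if (is.null(colorMeans)) {
    colorMeans <- rbind(benign = c(0.70, 0.52, 0.42),
                        malignant = c(0.24, 0.12, 0.10))
  }
  if (is.null(colorSpreads)) {
    colorSpreads <- rbind(benign = c(0.03, 0.03, 0.03),
                          malignant = c(0.09, 0.09, 0.09))
  }
  colnames(colorMeans) <- colnames(colorSpreads) <- c("r", "g", "b")
  new("SyntheticParams", nImages = nImages, classBalance = classBalance,
      imageSide = imageSide, lesionIrregularity = lesionIrregularity,
      colorMeans = colorMeans, colorSpreads = colorSpreads,
      hairProbability = hairProbability, seed = as.numeric(seed))
}

setMethod("show", "SyntheticParams", function(object) {
  cat(sprintf(
    "SyntheticParams: %d images (%.0f%% malignant), side %d, seed %d\n",
    object@nImages, 100 * object@classBalance, object@imageSide, object@seed))
})

#' Result of a stratified train/test split
#'
#' @slot trainRecords,testRecords data.frames of metadata records; disjoint,
#'   and their union is the input set.
#' @slot unlabeledMask logical, one entry per training record; `TRUE` marks
#'   records whose labels are withheld for semi-supervised training.
#' @export
setClass("SplitResult",
  slots = c(trainRecords = "data.frame", testRecords = "data.frame",
            unlabeledMask = "logical"))

setValidity("SplitResult", function(object) {
  if (length(object@unlabeledMask) != nrow(object@trainRecords)) {
    return("unlabeledMask length must match trainRecords rows")
  }
  both <- intersect(object@trainRecords$image_name,
                    object@testRecords$image_name)
  if (length(both) > 0L) return("train and test sets overlap")
  TRUE
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult: %d train (%d unlabeled), %d test\n",
              nrow(object@trainRecords), sum(object@unlabeledMask),
              nrow(object@testRecords)))
})

#' DCGAN generator network
#'
#' Five fractional-stride (transposed) convolution stages mapping a latent
#' vector to a 64 x 64 x 3 image: feature maps 512, 256, 128, 64, 3 at
#' spatial sizes 4, 8, 16, 32, 64; batch normalization and ReLU on all hidden
#' stages and a Tanh output scaling pixels into (-1, 1).
#'
#' @slot layers list of layer parameter sets (weights, biases, batch-norm
#'   state, stride/padding, activation tag).
#' @slot latentDim length of the latent input vector (default 100).
#' @export
setClass("GeneratorNet", slots = c(layers = "list", latentDim = "numeric"))

setValidity("GeneratorNet", function(object) {
  if (length(object@layers) != 5L) return("generator must have 5 layers")
  if (object@latentDim < 1) return("latentDim must be positive")
  TRUE
})

setMethod("show", "GeneratorNet", function(object) {
  cat(sprintf(
    "GeneratorNet: z[%d] -> 4x4x512 -> 8x8x256 -> 16x16x128 -> 32x32x64 -> 64x64x3 (Tanh)\n",
    object@latentDim))
})

#' DCGAN discriminator / semi-supervised classifier network
#'
#' Strided convolution tower mirroring the generator
#' (64x64x3 -> 32x32x64 -> 16x16x128 -> 8x8x256 -> 4x4x512) with LeakyReLU
#' (slope 0.2) activations, followed by a convolutional classifier stage with
#' an (N+1)-unit softmax head over \{benign, malignant, fake\}.
#'
#' @slot layers list of layer parameter sets.
#' @slot nClasses number of real classes N (head has N+1 units).
#' @export
setClass("DiscriminatorNet", slots = c(layers = "list", nClasses = "numeric"))

setValidity("DiscriminatorNet", function(object) {
  if (length(object@layers) != 5L) return("discriminator must have 5 layers")
  if (object@nClasses < 2) return("nClasses must be at least 2")
  TRUE
})

setMethod("show", "DiscriminatorNet", function(object) {
  cat(sprintf(
    "DiscriminatorNet: 64x64x3 -> 32x32x64 -> 16x16x128 -> 8x8x256 -> 4x4x512 -> %d-unit softmax\n",
    object@nClasses + 1))
})

#' Training hyperparameters for the DCGAN
#'
#' Defaults reproduce the published settings: SGDM with learning rate 0.01
#' and momentum 0.5, mini-batch 64, weight init N(0, 0.02^2), saturating
#' generator loss, validation every 50 iterations.
#'
#' @slot learningRate,momentum,batchSize,epochs,initStd,seed numeric scalars.
#' @slot generatorLossForm `"saturating"` (mean log(1 - p_real(fake)),
#'   minimized) or `"nonsaturating"` (mean -log p_real(fake)).
#' @slot validationFrequency iterations between validation-accuracy records.
#' @slot epsilon probability clamp used inside logarithms.
#' @export
setClass("TrainConfig",
  slots = c(learningRate = "numeric", momentum = "numeric",
            batchSize = "numeric", epochs = "numeric", initStd = "numeric",
            seed = "numeric", generatorLossForm = "character",
            validationFrequency = "numeric", epsilon = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@momentum < 0 || object@momentum >= 1) {
    return("momentum must lie in [0, 1)")
  }
  if (object@batchSize < 1) return("batchSize must be positive")
  if (object@epochs < 1) return("epochs must be positive")
  if (object@initStd <= 0) return("initStd must be positive")
  if (!object@generatorLossForm %in% c("saturating", "nonsaturating")) {
    return("generatorLossForm must be 'saturating' or 'nonsaturating'")
  }
  TRUE
})

#' @rdname TrainConfig-class
#' @param learningRate,momentum,batchSize,epochs,initStd,seed,generatorLossForm,validationFrequency,epsilon
#'   see the corresponding slots.
#' @export
TrainConfig <- function(learningRate = 0.01, momentum = 0.5, batchSize = 64,
                        epochs = 10, initStd = 0.02, seed = 1L,
                        generatorLossForm = "saturating",
                        validationFrequency = 50, epsilon = 1e-7) {
  new("TrainConfig", learningRate = learningRate, momentum = momentum,
      batchSize = batchSize, epochs = epochs, initStd = initStd,
      seed = as.numeric(seed), generatorLossForm = generatorLossForm,
      validationFrequency = validationFrequency, epsilon = epsilon)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: lr %g, momentum %g, batch %d, %d epochs, init sd %g, %s G-loss\n",
    object@learningRate, object@momentum, object@batchSize, object@epochs,
    object@initStd, object@generatorLossForm))
})

#' Per-iteration record of a DCGAN training run
#'
#' @slot iterations data.frame with one row per iteration: `iteration`,
#'   `epoch`, `d_score` (mean p_real on the real batch), `g_score` (mean
#'   p_real on the fake batch), `d_loss`, `d_real_loss`, `d_fake_loss`,
#'   `g_loss`, `supervised_loss`. `d_loss` equals
#'   `d_real_loss + d_fake_loss` at every iteration.
#' @slot validation data.frame of validation-accuracy records (`iteration`,
#'   `epoch`, `accuracy`); empty when no validation set was supplied.
#' @export
setClass("TrainingTrace",
  slots = c(iterations = "data.frame", validation = "data.frame"))

setMethod("show", "TrainingTrace", function(object) {
  it <- object@iterations
  cat(sprintf("TrainingTrace: %d iterations", nrow(it)))
  if (nrow(it) > 0L) {
    cat(sprintf(", final d_score %.3f, g_score %.3f, d_loss %.4f",
                it$d_score[nrow(it)], it$g_score[nrow(it)],
                it$d_loss[nrow(it)]))
  }
  cat("\n")
})

#' A discrete probability distribution over a finite symbol set
#'
#' Used as the analytic oracle for the GAN value function: the optimal
#' discriminator and the minimax equilibrium can be computed in closed form
#' on discrete distributions.
#'
#' @slot support character vector of symbols.
#' @slot probs nonnegative numeric summing to 1.
#' @export
setClass("DiscreteDistribution",
  slots = c(support = "character", probs = "numeric"))

setValidity("DiscreteDistribution", function(object) {
  if (length(object@support) != length(object@probs)) {
    return("support and probs must have the same length")
  }
  if (any(object@probs < 0)) return("probabilities must be nonnegative")
  if (abs(sum(object@probs) - 1) > 1e-12) {
    return("probabilities must sum to 1")
  }
  TRUE
})

#' @rdname DiscreteDistribution-class
#' @param probs nonnegative numeric summing to 1.
#' @param support symbol names; defaults to `s1, s2, ...`.
#' @export
DiscreteDistribution <- function(probs, support = NULL) {
  if (is.null(support)) support <- paste0("s", seq_along(probs))
  new("DiscreteDistribution", support = as.character(support),
      probs = as.numeric(probs))
}

#' Binary confusion matrix with malignant as the positive class
#'
#' @slot tp,tn,fp,fn nonnegative integer counts.
#' @export
setClass("ConfusionMatrix",
  slots = c(tp = "integer", tn = "integer", fp = "integer", fn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  counts <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(counts < 0L)) return("counts must be nonnegative")
  TRUE
})

#' @rdname ConfusionMatrix-class
#' @param tp,tn,fp,fn counts (malignant = positive class).
#' @export
ConfusionMatrix <- function(tp, tn, fp, fn) {
  new("ConfusionMatrix", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn))
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (malignant = positive)\n")
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2L, 2L,
              dimnames = list(true = c("malignant", "benign"),
                              predicted = c("malignant", "benign")))
  print(m)
})

#' Classification metrics report
#'
#' Confusion-matrix-derived metrics in percent, plus ROC/AUC when scores are
#' available. `bas` is the balanced accuracy score,
#' `(recall + specificity) / 2`. Metrics with a zero denominator are reported
#' as 0 and their names recorded in `degenerate`.
#'
#' @slot accuracy,precision,recall,specificity,f1,bas percentages.
#' @slot auc real in \[0, 1\] (`NA` when no scores were supplied).
#' @slot rocPoints data.frame with columns `fpr`, `tpr`.
#' @slot degenerate character vector naming zero-denominator metrics.
#' @export
setClass("MetricsReport",
  slots = c(accuracy = "numeric", precision = "numeric", recall = "numeric",
            specificity = "numeric", f1 = "numeric", bas = "numeric",
            auc = "numeric", rocPoints = "data.frame",
            degenerate = "character"))

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport: accuracy %.2f%%, recall %.2f%%, precision %.2f%%, specificity %.2f%%, F1 %.2f%%, BAS %.2f%%",
    object@accuracy, object@recall, object@precision, object@specificity,
    object@f1, object@bas))
  if (!is.na(object@auc)) cat(sprintf(", AUC %.4f", object@auc))
  cat("\n")
  if (length(object@degenerate) > 0L) {
    cat("  zero-denominator metrics reported as 0:",
        paste(object@degenerate, collapse = ", "), "\n")
  }
})

#' Image-quality report: MSE, PSNR and SSIM between two images
#'
#' `psnrDb` is `Inf` exactly when `mse` is 0; otherwise
#' `psnrDb == 10 * log10(MAX^2 / mse)`.
#'
#' @slot mse nonnegative real.
#' @slot psnrDb real or `Inf`.
#' @slot ssim real in \[-1, 1\].
#' @export
setClass("QualityReport",
  slots = c(mse = "numeric", psnrDb = "numeric", ssim = "numeric"))

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: MSE %.6g, PSNR %s dB, SSIM %.4f\n",
              object@mse,
              if (is.infinite(object@psnrDb)) "Inf"
              else sprintf("%.2f", object@psnrDb),
              object@ssim))
})
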