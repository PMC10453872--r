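# Improved DCGAN: network constructors, weight init, the minimax value
# function and its analytic optimal discriminator, loss closed forms, SGDM,
# and image generation. The training loop lives in gan_train.R.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1
LEAKY_SLOPE <- 0.2
TANH_MARGIN <- 1e-7

# ---- layer plumbing ---------------------------------------------------------

gen_layer_specs <- function(latentDim) {
  list(
    list(type = "tconv", k = 4L, inC = latentDim, outC = 512L, stride = 1L,
         pad = 0L, bn = TRUE, act = "relu"),
    list(type = "tconv", k = 4L, inC = 512L, outC = 256L, stride = 2L,
         pad = 1L, bn = TRUE, act = "relu"),
    list(type = "tconv", k = 4L, inC = 256L, outC = 128L, stride = 2L,
         pad = 1L, bn = TRUE, act = "relu"),
    list(type = "tconv", k = 4L, inC = 128L, outC = 64L, stride = 2L,
         pad = 1L, bn = TRUE, act = "relu"),
    list(type = "tconv", k = 4L, inC = 64L, outC = 3L, stride = 2L,
         pad = 1L, bn = FALSE, act = "tanh"))
}

disc_layer_specs <- function(nClasses) {
  list(
    list(type = "conv", k = 4L, inC = 3L, outC = 64L, stride = 2L,
         pad = 1L, bn = FALSE, act = "lrelu"),
    list(type = "conv", k = 4L, inC = 64L, outC = 128L, stride = 2L,
         pad = 1L, bn = TRUE, act = "lrelu"),
    list(type = "conv", k = 4L, inC = 128L, outC = 256L, stride = 2L,
         pad = 1L, bn = TRUE, act = "lrelu"),
    list(type = "conv", k = 4L, inC = 256L, outC = 512L, stride = 2L,
         pad = 1L, bn = TRUE, act = "lrelu"),
    list(type = "conv", k = 4L, inC = 512L, outC = nClasses + 1L,
         stride = 1L, pad = 0L, bn = FALSE, act = "linear"))
}

make_layer <- function(spec) {
  wdim <- if (spec$type == "conv") {
    c(spec$k, spec$k, spec$inC, spec$outC)
  } else {
    c(spec$k, spec$k, spec$outC, spec$inC)
  }
  layer <- list(type = spec$type, stride = spec$stride, pad = spec$pad,
                act = spec$act, W = array(0, wdim),
                b = numeric(spec$outC), bn = NULL)
  if (isTRUE(spec$bn)) {
    layer$bn <- list(gamma = rep(1, spec$outC), beta = numeric(spec$outC),
                     runMean = numeric(spec$outC), runVar = rep(1, spec$outC))
  }
  layer
}

#' Build the DCGAN generator
#'
#' Five transposed-convolution stages (4 x 4 kernels; the first stage maps
#' the latent vector to 4 x 4 x 512 with stride 1 and no padding, the rest
#' use stride 2 and padding 1) with batch normalization and ReLU on hidden
#' stages and a Tanh output: z -> 4x4x512 -> 8x8x256 -> 16x16x128 ->
#' 32x32x64 -> 64x64x3.
#'
#' @param latentDim latent vector length (default 100).
#' @param seed integer seed for the weight initialization.
#' @param initStd weight init standard deviation (default 0.02).
#' @return a [GeneratorNet-class] with N(0, initStd^2) weights, zero biases.
#' @export
buildGenerator <- function(latentDim = 100L, seed = 1L, initStd = 0.02) {
  if (latentDim < 1) stop("latentDim must be at least 1")
  net <- new("GeneratorNet",
             layers = lapply(gen_layer_specs(as.integer(latentDim)),
                             make_layer),
             latentDim = as.numeric(latentDim))
  initWeights(net, seed = seed, std = initStd)
}

#' Build the DCGAN discriminator / classifier
#'
#' Four strided convolution stages (LeakyReLU 0.2, batch norm on all but the
#' first) mirroring the generator, plus a convolutional classifier stage with
#' an (nClasses + 1)-unit softmax head: 64x64x3 -> 32x32x64 -> 16x16x128 ->
#' 8x8x256 -> 4x4x512 -> (N+1) units. The extra unit is the fake class;
#' `p_real = 1 - p_fake` identically.
#'
#' @param nClasses number of real classes (>= 2; default 2 for
#'   benign/malignant).
#' @param seed integer seed for the weight initialization.
#' @param initStd weight init standard deviation (default 0.02).
#' @return a [DiscriminatorNet-class].
#' @export
buildDiscriminator <- function(nClasses = 2L, seed = 1L, initStd = 0.02) {
  if (nClasses < 2) stop("nClasses must be at least 2")
  net <- new("DiscriminatorNet",
             layers = lapply(disc_layer_specs(as.integer(nClasses)),
                             make_layer),
             nClasses = as.numeric(nClasses))
  initWeights(net, seed = seed, std = initStd)
}

#' Initialize network weights
#'
#' All convolution weights are drawn from N(0, std^2); all biases (and batch
#' norm shifts) are zero; batch norm scales start at 1. Identical seeds give
#' identical weights.
#'
#' @param net a [GeneratorNet-class] or [DiscriminatorNet-class].
#' @param seed integer seed.
#' @param std standard deviation (> 0), default 0.02.
#' @return the network with re-initialized weights.
#' @export
initWeights <- function(net, seed = 1L, std = 0.02) {
  if (std <= 0) stop("std must be positive")
  net@layers <- with_seed(seed, {
    lapply(net@layers, function(layer) {
      layer$W <- array(rnorm(length(layer$W), 0, std), dim(layer$W))
      layer$b <- numeric(length(layer$b))
      if (!is.null(layer$bn)) {
        layer$bn$gamma <- rep(1, length(layer$bn$gamma))
        layer$bn$beta <- numeric(length(layer$bn$beta))
        layer$bn$runMean <- numeric(length(layer$bn$runMean))
        layer$bn$runVar <- rep(1, length(layer$bn$runVar))
      }
      layer
    })
  })
  net
}

# ---- forward / backward -----------------------------------------------------

# expand a per-channel constant to the full (H, W, F, N) array layout
per_channel <- function(v, d) {
  rep(rep(v, each = d[1L] * d[2L]), times = d[4L])
}

# per-channel sums over (H, W, N); x dims (H, W, F, N)
channel_sums <- function(x, d) {
  .rowSums(matrix(.colSums(x, d[1L] * d[2L], d[3L] * d[4L]),
                  d[3L], d[4L]), d[3L], d[4L])
}

# batch norm over (H, W, N) per channel; x dims (H, W, F, N). Cache stores
# only per-channel statistics; xhat is recomputed in the backward pass.
bn_forward <- function(x, bn, training, updateRunning = TRUE) {
  d <- dim(x)
  m <- d[1L] * d[2L] * d[4L]
  if (training) {
    mu <- channel_sums(x, d) / m
    v <- pmax(channel_sums(x * x, d) / m - mu^2, 0)
    if (updateRunning) {
      bn$runMean <- (1 - BN_MOMENTUM) * bn$runMean + BN_MOMENTUM * mu
      bn$runVar <- (1 - BN_MOMENTUM) * bn$runVar + BN_MOMENTUM * v
    }
  } else {
    mu <- bn$runMean
    v <- bn$runVar
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  scale <- bn$gamma * invstd
  shift <- bn$beta - mu * scale
  y <- x * per_channel(scale, d) + per_channel(shift, d)
  dim(y) <- d
  list(y = y, bn = bn,
       cache = list(mu = mu, invstd = invstd, d = d, x = x))
}

bn_backward <- function(dy, bn, cache) {
  d <- cache$d
  m <- d[1L] * d[2L] * d[4L]
  xhat <- (cache$x - per_channel(cache$mu, d)) * per_channel(cache$invstd, d)
  dgamma <- channel_sums(dy * xhat, d)
  dbeta <- channel_sums(dy, d)
  dx <- (dy - per_channel(dbeta / m, d) - xhat * per_channel(dgamma / m, d)) *
    per_channel(bn$gamma * cache$invstd, d)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

activate <- function(a, act) {
  switch(act,
    relu = pmax(a, 0),
    lrelu = pmax(a, 0) + LEAKY_SLOPE * pmin(a, 0),
    tanh = clip_range(tanh(a), -1 + TANH_MARGIN, 1 - TANH_MARGIN),
    linear = a)
}

activate_bwd <- function(dy, a, act) {
  switch(act,
    relu = dy * (a > 0),
    lrelu = dy * (LEAKY_SLOPE + (1 - LEAKY_SLOPE) * (a > 0)),
    tanh = dy * (1 - tanh(a)^2),
    linear = dy)
}

# x dims (H, W, C, N); returns activations, caches and (possibly) updated
# batch-norm running statistics
net_forward_full <- function(layers, x, training = FALSE,
                             updateRunning = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    layer <- layers[[i]]
    z <- if (layer$type == "conv") {
      .cpp_conv2d_fwd(x, layer$W, layer$b, layer$stride, layer$pad)
    } else {
      .cpp_tconv2d_fwd(x, layer$W, layer$b, layer$stride, layer$pad)
    }
    bncache <- NULL
    a <- z
    if (!is.null(layer$bn)) {
      bf <- bn_forward(z, layer$bn, training, updateRunning)
      a <- bf$y
      layers[[i]]$bn <- bf$bn
      bncache <- bf$cache
    }
    out <- activate(a, layer$act)
    caches[[i]] <- list(x = x, pre = a, bncache = bncache)
    x <- out
  }
  list(out = x, caches = caches, layers = layers)
}

# dout: gradient w.r.t. the network output; returns per-layer parameter
# gradients and the gradient w.r.t. the network input
net_backward_full <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  dy <- dout
  for (i in rev(seq_along(layers))) {
    layer <- layers[[i]]
    cache <- caches[[i]]
    da <- activate_bwd(dy, cache$pre, layer$act)
    g <- list(W = NULL, b = NULL, gamma = NULL, beta = NULL)
    if (!is.null(layer$bn)) {
      bb <- bn_backward(da, layer$bn, cache$bncache)
      da <- bb$dx
      g$gamma <- bb$dgamma
      g$beta <- bb$dbeta
    }
    cb <- if (layer$type == "conv") {
      .cpp_conv2d_bwd(cache$x, layer$W, da, layer$stride, layer$pad)
    } else {
      .cpp_tconv2d_bwd(cache$x, layer$W, da, layer$stride, layer$pad)
    }
    g$W <- cb$dW
    g$b <- cb$db
    grads[[i]] <- g
    dy <- cb$dx
  }
  list(grads = grads, dx = dy)
}

#' Forward pass through a network
#'
#' For a [GeneratorNet-class], `input` is a latentDim x n matrix of latent
#' vectors (or a single vector) and the result is a (64, 64, 3, n) array of
#' Tanh-bounded pixel values. For a [DiscriminatorNet-class], `input` is a
#' (64, 64, 3, n) array in \[-1, 1\] and the result is an n x (N+1) matrix of
#' softmax probabilities over \{benign, malignant, fake\} summing to 1 per
#' row. Batch-norm uses running statistics (inference mode).
#'
#' @param net the network.
#' @param input latent matrix or image batch array.
#' @return images array or probability matrix.
#' @export
setGeneric("netForward", function(net, input) standardGeneric("netForward"))

#' @rdname netForward
setMethod("netForward", "GeneratorNet", function(net, input) {
  if (is.vector(input)) input <- matrix(input, ncol = 1L)
  if (nrow(input) != net@latentDim) {
    stop("latent vectors must have length ", net@latentDim)
  }
  x <- array(0, c(1L, 1L, nrow(input), ncol(input)))
  x[1L, 1L, , ] <- input
  net_forward_full(net@layers, x, training = FALSE)$out
})

#' @rdname netForward
setMethod("netForward", "DiscriminatorNet", function(net, input) {
  if (length(dim(input)) == 3L) input <- array(input, c(dim(input), 1L))
  logits <- disc_logits(net@layers, input, training = FALSE)$logits
  softmax_rows(logits)
})

disc_logits <- function(layers, x, training, updateRunning = TRUE) {
  ff <- net_forward_full(layers, x, training, updateRunning)
  nUnits <- dim(ff$out)[3L]
  n <- dim(ff$out)[4L]
  list(logits = t(matrix(ff$out, nUnits, n)), caches = ff$caches,
       layers = ff$layers)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- analytic oracle: value function on discrete distributions --------------

dist_probs <- function(p) {
  if (methods::is(p, "DiscreteDistribution")) {
    methods::validObject(p)
    p@probs
  } else {
    as.numeric(p)
  }
}

#' Optimal discriminator for the minimax value function
#'
#' On discrete distributions the discriminator maximizing the GAN value
#' function is `D*(x) = p_data(x) / (p_data(x) + p_g(x))`; when the
#' generated distribution equals the data distribution, `D*` is 1/2
#' everywhere — the score the trained discriminator approaches at
#' equilibrium. Symbols with zero probability under both distributions get
#' 1/2 by convention.
#'
#' @param pData,pG [DiscreteDistribution-class] objects (or probability
#'   vectors) on a shared support.
#' @return numeric vector of per-symbol optimal discriminator outputs.
#' @examples
#' optimalDiscriminator(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5))  # all 0.5
#' @export
optimalDiscriminator <- function(pData, pG) {
  pd <- dist_probs(pData)
  pg <- dist_probs(pG)
  if (length(pd) != length(pg)) stop("distributions must share a support")
  both0 <- pd + pg == 0
  out <- rep(0.5, length(pd))
  out[!both0] <- pd[!both0] / (pd[!both0] + pg[!both0])
  out
}

#' GAN minimax value function on discrete distributions
#'
#' `V(D) = sum_x p_data(x) log D(x) + sum_x p_g(x) log(1 - D(x))`. Maximized
#' over D at [optimalDiscriminator()]; at equilibrium (p_g = p_data,
#' D = 1/2) the value is `-2 log 2`.
#'
#' @param pData,pG [DiscreteDistribution-class] objects or probability
#'   vectors.
#' @param D per-symbol discriminator outputs, all strictly inside (0, 1).
#' @return scalar value of the game.
#' @examples
#' valueFunction(c(0.2, 0.8), c(0.5, 0.5), c(0.5, 0.5))  # -2 log 2
#' @export
valueFunction <- function(pData, pG, D) {
  pd <- dist_probs(pData)
  pg <- dist_probs(pG)
  if (length(pd) != length(D) || length(pg) != length(D)) {
    stop("D must give one value per support symbol")
  }
  if (any(D <= 0) || any(D >= 1)) stop("D values must lie strictly in (0, 1)")
  sum(pd * log(D)) + sum(pg * log(1 - D))
}

# ---- loss closed forms ------------------------------------------------------

#' Supervised cross-entropy loss
#'
#' Mean over samples of the negative log-probability assigned to the true
#' class. Zero probabilities are clamped at `epsilon` (with a message), so
#' the loss stays finite.
#'
#' @param classProbs n x K matrix of per-sample class probabilities (rows sum
#'   to 1).
#' @param labels integer true-class indices in 1..K.
#' @param epsilon clamp for log arguments.
#' @return nonnegative scalar.
#' @examples
#' supervisedLoss(matrix(1 / 3, 1, 3), 1L)  # log(3)
#' @export
supervisedLoss <- function(classProbs, labels, epsilon = 1e-7) {
  classProbs <- rbind(classProbs)
  labels <- as.integer(labels)
  if (length(labels) != nrow(classProbs)) {
    stop("one label per probability row required")
  }
  if (any(labels < 1L | labels > ncol(classProbs))) {
    stop("labels must index probability columns")
  }
  if (any(abs(rowSums(classProbs) - 1) > 1e-6)) {
    stop("probability rows must sum to 1")
  }
  p <- classProbs[cbind(seq_along(labels), labels)]
  if (any(p < epsilon)) {
    message("supervisedLoss: ", sum(p < epsilon),
            " true-class probabilities clamped at epsilon")
    p <- pmax(p, epsilon)
  }
  mean(-log(p))
}

#' Discriminator adversarial loss and its decomposition
#'
#' `d_real_loss = mean(-log p_real(real))`,
#' `d_fake_loss = mean(-log(1 - p_real(fake)))`, and their sum `d_loss`.
#' A perfect discriminator scores 0; at the 0.5 equilibrium the total is
#' `2 log 2`.
#'
#' @param pRealOnReal probabilities the discriminator assigns to real inputs
#'   being real.
#' @param pRealOnFake probabilities assigned to generated inputs being real.
#' @param epsilon clamp for log arguments.
#' @return named numeric: `dLoss`, `dRealLoss`, `dFakeLoss`
#'   (`dLoss == dRealLoss + dFakeLoss`).
#' @examples
#' discriminatorLoss(0.5, 0.5)[["dLoss"]]  # 2 log 2
#' @export
discriminatorLoss <- function(pRealOnReal, pRealOnFake, epsilon = 1e-7) {
  pr <- clip_range(pRealOnReal, epsilon, 1 - epsilon)
  pf <- clip_range(pRealOnFake, epsilon, 1 - epsilon)
  dReal <- mean(-log(pr))
  dFake <- mean(-log(1 - pf))
  c(dLoss = dReal + dFake, dRealLoss = dReal, dFakeLoss = dFake)
}

#' Generator adversarial loss
#'
#' The saturating form is the quantity the generator minimizes in the
#' original minimax game, `mean(log(1 - p_real(fake)))`; the nonsaturating
#' alternative `mean(-log p_real(fake))` has the same fixed points but
#' stronger gradients early in training.
#'
#' @param pRealOnFake probabilities the discriminator assigns to generated
#'   inputs being real.
#' @param form `"saturating"` or `"nonsaturating"`.
#' @param epsilon clamp for log arguments.
#' @return scalar loss (saturating form is negative for p > 0).
#' @export
generatorLoss <- function(pRealOnFake, form = c("saturating", "nonsaturating"),
                          epsilon = 1e-7) {
  form <- match.arg(form)
  p <- clip_range(pRealOnFake, epsilon, 1 - epsilon)
  if (form == "saturating") mean(log(1 - p)) else mean(-log(p))
}

# ---- head gradients (w.r.t. pre-softmax logits) -----------------------------

onehot <- function(idx, k) {
  m <- matrix(0, length(idx), k)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# grad of mean -log p_label w.r.t. logits
grad_ce <- function(logits, labels) {
  P <- softmax_rows(logits)
  (P - onehot(labels, ncol(logits))) / nrow(logits)
}

# grad of mean -log(1 - p_fake) w.r.t. logits (used on real batches, and for
# the nonsaturating generator objective)
grad_not_fake <- function(logits, fakeIdx, epsilon = 1e-7) {
  P <- softmax_rows(logits)
  pf <- P[, fakeIdx]
  coef <- pf / pmax(1 - pf, epsilon)
  g <- -P * coef
  g[, fakeIdx] <- g[, fakeIdx] + coef
  g / nrow(logits)
}

# grad of mean log p_fake w.r.t. logits (saturating generator objective)
grad_log_fake <- function(logits, fakeIdx) {
  P <- softmax_rows(logits)
  g <- -P
  g[, fakeIdx] <- g[, fakeIdx] + 1
  g / nrow(logits)
}

# loss values from logits, used by the finite-difference gradient tests
sup_loss_from_logits <- function(logits, labels, epsilon = 1e-7) {
  supervisedLoss(softmax_rows(logits), labels, epsilon)
}

adv_loss_from_logits <- function(logitsReal, logitsFake, fakeIdx,
                                 epsilon = 1e-7) {
  pRealR <- 1 - softmax_rows(logitsReal)[, fakeIdx]
  pRealF <- 1 - softmax_rows(logitsFake)[, fakeIdx]
  discriminatorLoss(pRealR, pRealF, epsilon)[["dLoss"]]
}

# ---- SGDM -------------------------------------------------------------------

#' Stochastic gradient descent with classical momentum
#'
#' `v <- momentum * v - lr * g; w <- w + v`, applied elementwise. Operates on
#' numeric arrays or arbitrarily nested lists of them (a network's parameter
#' set); a `NULL` velocity starts at zero.
#'
#' @param weights numeric array or nested list of arrays.
#' @param gradients matching structure of gradients.
#' @param velocity matching structure of velocities, or `NULL`.
#' @param lr learning rate.
#' @param momentum momentum coefficient in \[0, 1).
#' @return list with updated `weights` and `velocity`.
#' @examples
#' s <- sgdmUpdate(0, 1, NULL, lr = 0.1, momentum = 0.5)
#' s <- sgdmUpdate(s$weights, 1, s$velocity, lr = 0.1, momentum = 0.5)
#' s$weights  # -0.25 after two steps
#' @export
sgdmUpdate <- function(weights, gradients, velocity = NULL, lr, momentum) {
  if (is.numeric(weights)) {
    if (!is.numeric(gradients) || length(gradients) != length(weights)) {
      stop("gradient shape does not match weights")
    }
    if (is.null(velocity)) velocity <- weights * 0
    v <- momentum * velocity - lr * gradients
    return(list(weights = weights + v, velocity = v))
  }
  if (is.null(weights)) return(list(weights = NULL, velocity = NULL))
  if (is.list(weights)) {
    if (is.null(velocity)) velocity <- vector("list", length(weights))
    w <- v <- vector("list", length(weights))
    names(w) <- names(v) <- names(weights)
    for (i in seq_along(weights)) {
      s <- sgdmUpdate(weights[[i]], gradients[[i]], velocity[[i]], lr,
                      momentum)
      w[[i]] <- s$weights
      v[[i]] <- s$velocity
    }
    return(list(weights = w, velocity = v))
  }
  stop("weights must be numeric or a list")
}

# parameter structure <-> layers
layers_params <- function(layers) {
  lapply(layers, function(l) {
    list(W = l$W, b = l$b,
         gamma = if (is.null(l$bn)) NULL else l$bn$gamma,
         beta = if (is.null(l$bn)) NULL else l$bn$beta)
  })
}

layers_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    layers[[i]]$W <- params[[i]]$W
    layers[[i]]$b <- params[[i]]$b
    if (!is.null(layers[[i]]$bn)) {
      layers[[i]]$bn$gamma <- params[[i]]$gamma
      layers[[i]]$bn$beta <- params[[i]]$beta
    }
  }
  layers
}

grads_params <- function(grads) {
  lapply(grads, function(g) {
    list(W = g$W, b = g$b, gamma = g$gamma, beta = g$beta)
  })
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- a
  for (i in seq_along(a)) out[[i]] <- add_grads(a[[i]], b[[i]])
  out
}

# ---- generation -------------------------------------------------------------

#' Sample images from a trained generator
#'
#' Draws n latent vectors from the standard normal prior, runs the generator
#' (inference-mode batch norm), and rescales outputs from the Tanh range
#' (-1, 1) to \[0, 1\].
#'
#' @param G a [GeneratorNet-class].
#' @param n number of images (>= 1).
#' @param seed integer seed; identical (G, seed) give identical batches.
#' @return list of n RGB [ImageTensor-class] objects in \[0, 1\].
#' @export
generateImages <- function(G, n, seed = 1L) {
  if (n < 1) stop("n must be at least 1")
  z <- with_seed(seed, matrix(rnorm(G@latentDim * n), G@latentDim, n))
  raw <- netForward(G, z)
  lapply(seq_len(n), function(i) {
    ImageTensor((raw[, , , i] + 1) / 2, c(0, 1), "RGB")
  })
}

#' Stack images into a network input batch
#'
#' Converts a list of RGB images in \[0, 1\] into the (64, 64, 3, n) array in
#' \[-1, 1\] the discriminator consumes.
#'
#' @param images list of [ImageTensor-class] objects with identical
#'   dimensions.
#' @return numeric array (H, W, C, n) in \[-1, 1\].
#' @export
imagesToBatch <- function(images) {
  stopifnot(length(images) > 0L)
  d <- dim(images[[1L]]@pixels)
  out <- array(0, c(d, length(images)))
  for (i in seq_along(images)) {
    img <- images[[i]]
    vr <- img@valueRange
    out[, , , i] <- (img@pixels - vr[1L]) / (vr[2L] - vr[1L]) * 2 - 1
  }
  out
}
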