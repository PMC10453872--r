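# Network architecture contracts, analytic oracles, loss closed forms,
# gradients, SGDM, and a short seeded training smoke run.

test_that("generator emits 64x64x3 Tanh-bounded images through the declared stages", {
  G <- buildGenerator(latentDim = 100, seed = 1)
  expect_equal(length(G@layers), 5L)
  z <- withr::with_seed(2, matrix(rnorm(100 * 2), 100, 2))
  ff <- lesiongan:::net_forward_full(G@layers, lesiongan:::z_input(z))
  expect_equal(dim(ff$out), c(64L, 64L, 3L, 2L))
  expect_true(all(ff$out > -1 & ff$out < 1))
  # intermediate activation shapes: 4^2x512, 8^2x256, 16^2x128, 32^2x64
  shapes <- lapply(ff$caches[2:5], function(cc) dim(cc$x)[1:3])
  expect_equal(shapes[[1]], c(4L, 4L, 512L))
  expect_equal(shapes[[2]], c(8L, 8L, 256L))
  expect_equal(shapes[[3]], c(16L, 16L, 128L))
  expect_equal(shapes[[4]], c(32L, 32L, 64L))

  # seeded init is bit-identical
  G2 <- buildGenerator(latentDim = 100, seed = 1)
  expect_identical(G@layers[[3]]$W, G2@layers[[3]]$W)
  expect_error(buildGenerator(latentDim = 0), "at least 1")
})

test_that("discriminator head has N+1 softmax units and LeakyReLU 0.2 hidden stages", {
  D <- buildDiscriminator(nClasses = 2, seed = 5)
  expect_equal(length(D@layers), 5L)
  x <- withr::with_seed(6, array(runif(64 * 64 * 3 * 3, -1, 1),
                                 c(64, 64, 3, 3)))
  p <- netForward(D, x)
  expect_equal(dim(p), c(3L, 3L))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  expect_true(all(p > 0))
  # p_real == 1 - p_fake by construction of the head mapping
  expect_equal(1 - p[, 3], rowSums(p[, 1:2]), tolerance = 1e-12)

  expect_equal(lesiongan:::activate(-1, "lrelu"), -0.2)
  expect_equal(lesiongan:::activate(2, "lrelu"), 2)
  expect_error(buildDiscriminator(nClasses = 1), "at least 2")
})

test_that("initWeights draws N(0, 0.02) conv weights and zero biases", {
  G <- buildGenerator(seed = 11)
  D <- buildDiscriminator(seed = 12)
  allW <- unlist(c(lapply(G@layers, `[[`, "W"), lapply(D@layers, `[[`, "W")))
  expect_gt(length(allW), 1e4)
  expect_lt(abs(sd(allW) - 0.02) / 0.02, 0.05)
  expect_lt(abs(mean(allW)), 0.001)
  allB <- unlist(c(lapply(G@layers, `[[`, "b"), lapply(D@layers, `[[`, "b")))
  expect_true(all(allB == 0))
  # same seed -> identical weights
  expect_identical(initWeights(G, seed = 42)@layers[[2]]$W,
                   initWeights(G, seed = 42)@layers[[2]]$W)
})

test_that("optimal discriminator matches formula, convention and grid search", {
  p <- DiscreteDistribution(c(0.2, 0.3, 0.5))
  expect_equal(optimalDiscriminator(p, p), rep(0.5, 3))
  expect_equal(optimalDiscriminator(c(1, 0), c(0, 1)), c(1, 0))
  expect_equal(optimalDiscriminator(c(0.5, 0.5, 0), c(0.5, 0.5, 0))[3], 0.5)

  # brute-force grid search over per-symbol D values (the value function is
  # separable per symbol)
  grid <- seq(0.001, 0.999, by = 0.001)
  withr::with_seed(31, {
    for (rep in 1:5) {
      pd <- runif(3)
      pd <- pd / sum(pd)
      pg <- runif(3)
      pg <- pg / sum(pg)
      best <- vapply(1:3, function(i) {
        vals <- pd[i] * log(grid) + pg[i] * log(1 - grid)
        grid[which.max(vals)]
      }, numeric(1))
      expect_lt(max(abs(best - optimalDiscriminator(pd, pg))), 1e-3)
    }
  })
})

test_that("value function reaches -2 log 2 at equilibrium and peaks at D*", {
  pd <- c(0.2, 0.3, 0.5)
  expect_equal(valueFunction(pd, pd, rep(0.5, 3)), -2 * log(2))
  expect_equal(valueFunction(c(0.9, 0.1), c(0.4, 0.6), c(0.5, 0.5)),
               -2 * log(2))
  # perturbation: V is maximized at the analytic optimum
  pg <- c(0.5, 0.25, 0.25)
  Dstar <- optimalDiscriminator(pd, pg)
  vStar <- valueFunction(pd, pg, Dstar)
  for (i in 1:3) {
    for (dlt in c(-0.01, 0.01)) {
      Dp <- Dstar
      Dp[i] <- Dp[i] + dlt
      expect_lt(valueFunction(pd, pg, Dp), vStar)
    }
  }
  expect_error(valueFunction(pd, pg, c(0.5, 1, 0.5)), "strictly")
})

test_that("loss closed forms hold", {
  # supervised cross-entropy
  expect_equal(supervisedLoss(matrix(c(1, 0, 0), 1), 1L), 0)
  expect_equal(supervisedLoss(matrix(1 / 3, 1, 3), 2L), log(3),
               tolerance = 1e-9)
  probs <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.6, 0.3))
  expect_equal(supervisedLoss(probs, c(1L, 2L)),
               mean(c(-log(0.7), -log(0.6))), tolerance = 1e-12)
  expect_error(supervisedLoss(rbind(c(0.5, 0.2)), 1L), "sum to 1")

  # discriminator loss decomposition
  perfect <- discriminatorLoss(1, 0)
  expect_lt(perfect[["dLoss"]], 1e-5)
  half <- discriminatorLoss(0.5, 0.5)
  expect_equal(half[["dLoss"]], 2 * log(2), tolerance = 1e-6)
  mix <- discriminatorLoss(0.9, 0.2)
  expect_equal(mix[["dRealLoss"]], -log(0.9), tolerance = 1e-6)
  expect_equal(mix[["dFakeLoss"]], -log(0.8), tolerance = 1e-6)
  expect_equal(mix[["dLoss"]], 0.3285, tolerance = 1e-3)
  expect_equal(mix[["dLoss"]], mix[["dRealLoss"]] + mix[["dFakeLoss"]])

  # generator loss, both forms
  expect_equal(generatorLoss(0.5, "saturating"), log(0.5), tolerance = 1e-6)
  expect_equal(generatorLoss(0.5, "nonsaturating"), log(2), tolerance = 1e-6)
  # saturating form decreases monotonically as fakes look more real
  ps <- c(0.1, 0.5, 0.9, 0.99)
  expect_true(all(diff(vapply(ps, generatorLoss, numeric(1))) < 0))
})

test_that("head gradients match central finite differences", {
  withr::with_seed(41, {
    logits <- matrix(rnorm(4 * 3), 4, 3)
    labels <- sample(1:2, 4, replace = TRUE)
    logitsF <- matrix(rnorm(4 * 3), 4, 3)
  })
  h <- 1e-5

  gSup <- lesiongan:::grad_ce(logits, labels)
  for (i in seq_along(logits)) {
    lp <- lm <- logits
    lp[i] <- lp[i] + h
    lm[i] <- lm[i] - h
    fd <- (lesiongan:::sup_loss_from_logits(lp, labels) -
             lesiongan:::sup_loss_from_logits(lm, labels)) / (2 * h)
    expect_lt(abs(fd - gSup[i]), 1e-4)
  }

  # adversarial d_loss w.r.t. real-batch and fake-batch logits
  gReal <- lesiongan:::grad_not_fake(logits, 3L)
  gFake <- lesiongan:::grad_ce(logitsF, rep(3L, 4))
  for (i in seq_along(logits)) {
    lp <- lm <- logits
    lp[i] <- lp[i] + h
    lm[i] <- lm[i] - h
    fd <- (lesiongan:::adv_loss_from_logits(lp, logitsF, 3L) -
             lesiongan:::adv_loss_from_logits(lm, logitsF, 3L)) / (2 * h)
    expect_lt(abs(fd - gReal[i]), 1e-4)
    fp <- fm <- logitsF
    fp[i] <- fp[i] + h
    fm[i] <- fm[i] - h
    fdF <- (lesiongan:::adv_loss_from_logits(logits, fp, 3L) -
              lesiongan:::adv_loss_from_logits(logits, fm, 3L)) / (2 * h)
    expect_lt(abs(fdF - gFake[i]), 1e-4)
  }
})

test_that("sgdm follows the classical momentum recursion", {
  # momentum 0: plain gradient descent
  s <- sgdmUpdate(1, 0.5, NULL, lr = 0.1, momentum = 0)
  expect_equal(s$weights, 1 - 0.1 * 0.5)
  # zero gradient: pure velocity decay
  s2 <- sgdmUpdate(1, 0, 0.2, lr = 0.1, momentum = 0.5)
  expect_equal(s2$weights, 1 + 0.5 * 0.2)
  # hand recursion: w = -0.1 then -0.25
  s3 <- sgdmUpdate(0, 1, NULL, lr = 0.1, momentum = 0.5)
  expect_equal(s3$weights, -0.1)
  s4 <- sgdmUpdate(s3$weights, 1, s3$velocity, lr = 0.1, momentum = 0.5)
  expect_equal(s4$weights, -0.25)
  # nested structures
  w <- list(a = matrix(1, 2, 2), b = list(c = rep(0, 3)))
  g <- list(a = matrix(1, 2, 2), b = list(c = rep(2, 3)))
  s5 <- sgdmUpdate(w, g, NULL, lr = 0.1, momentum = 0.9)
  expect_equal(s5$weights$a, matrix(0.9, 2, 2))
  expect_equal(s5$weights$b$c, rep(-0.2, 3))
  expect_error(sgdmUpdate(1:3, 1:2, NULL, lr = 0.1, momentum = 0), "shape")
})

test_that("generated images are seeded, bounded, and correctly scaled", {
  G <- buildGenerator(seed = 51)
  imgs <- generateImages(G, 3, seed = 52)
  expect_length(imgs, 3)
  for (im in imgs) {
    expect_identical(dim(im), c(64L, 64L, 3L))
    expect_true(all(im@pixels >= 0 & im@pixels <= 1))
  }
  # pre-rescale values strictly inside (-1, 1)
  z <- withr::with_seed(52, matrix(rnorm(G@latentDim * 3), G@latentDim, 3))
  raw <- netForward(G, z)
  expect_true(all(raw > -1 & raw < 1))
  imgs2 <- generateImages(G, 3, seed = 52)
  expect_identical(imgs[[1]]@pixels, imgs2[[1]]@pixels)
})

test_that("a short seeded run keeps finite losses and exact trace bookkeeping", {
  withr::with_seed(61, {
    xs <- array(runif(64 * 64 * 3 * 64, -1, 1), c(64, 64, 3, 64))
    ys <- rep(0:1, 32)
  })
  mask <- rep(c(FALSE, FALSE, FALSE, TRUE), 16)  # 25% unlabeled
  cfg <- TrainConfig(batchSize = 16, epochs = 2, seed = 62)
  fit <- trainDcgan(xs, ys, mask, cfg)
  it <- fit$trace@iterations
  # epochs x floor(n/batch) iterations
  expect_equal(nrow(it), 2 * (64 %/% 16))
  expect_true(all(is.finite(unlist(it[, c("d_loss", "d_real_loss",
                                          "d_fake_loss", "g_loss")]))))
  # Eq. 3 decomposition at every iteration
  expect_lt(max(abs(it$d_loss - (it$d_real_loss + it$d_fake_loss))), 1e-9)
  # scores are probabilities
  expect_true(all(it$d_score > 0 & it$d_score < 1))
  expect_true(all(it$g_score > 0 & it$g_score < 1))

  # reruns with the same config are identical
  fit2 <- trainDcgan(xs, ys, mask, cfg)
  expect_identical(fit$trace@iterations, fit2$trace@iterations)

  expect_error(trainDcgan(xs, ys, rep(TRUE, 64), cfg), "labeled")
  expect_error(trainDcgan(xs, ys, mask, TrainConfig(batchSize = 128)),
               "exceeds")
})
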