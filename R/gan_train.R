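# The semi-supervised DCGAN training loop.
#
# Per minibatch: one combined discriminator step — adversarial loss on the
# real and generated batches plus supervised cross-entropy on the labeled
# real samples, backpropagated through the conv tower and applied with a
# single SGDM update — then one generator step with the discriminator
# frozen. Every iteration is traced.

#' Train the DCGAN classifier
#'
#' Trains generator and discriminator jointly. The discriminator's
#' (N+1)-unit softmax head receives three gradient contributions per
#' minibatch: push real inputs away from the fake class
#' (`-log p_real`), push generated inputs toward it (`-log p_fake`), and
#' standard cross-entropy toward the true class on the labeled subset. The
#' generator then takes one step against the frozen discriminator using the
#' configured loss form. The run is fully seeded: identical inputs and
#' config give an identical trace.
#'
#' @param trainImages (64, 64, 3, n) array in \[-1, 1\] (see
#'   [imagesToBatch()]).
#' @param trainLabels integer vector of targets (0 = benign, 1 = malignant);
#'   entries under the unlabeled mask are ignored.
#' @param unlabeledMask logical vector marking records whose labels are
#'   withheld; default all labeled.
#' @param cfg a [TrainConfig-class].
#' @param valImages,valLabels optional held-out set; accuracy is recorded
#'   every `validationFrequency` iterations and at the end of training.
#' @return list with elements `generator`, `discriminator` and `trace` (a
#'   [TrainingTrace-class]).
#' @export
trainDcgan <- function(trainImages, trainLabels,
                       unlabeledMask = rep(FALSE, length(trainLabels)),
                       cfg = TrainConfig(), valImages = NULL,
                       valLabels = NULL) {
  methods::validObject(cfg)
  n <- dim(trainImages)[4L]
  if (length(trainLabels) != n || length(unlabeledMask) != n) {
    stop("labels and unlabeled mask must have one entry per image")
  }
  if (!any(!unlabeledMask)) stop("at least one labeled training image needed")
  batch <- as.integer(cfg@batchSize)
  if (batch > n) stop("batch size exceeds the dataset size")
  eps <- cfg@epsilon
  labels1 <- as.integer(trainLabels) + 1L  # class indices 1 = benign, 2 = malignant

  G <- buildGenerator(seed = child_seed(cfg@seed, 101L), initStd = cfg@initStd)
  D <- buildDiscriminator(seed = child_seed(cfg@seed, 202L),
                          initStd = cfg@initStd)
  fakeIdx <- as.integer(D@nClasses) + 1L
  latentDim <- as.integer(G@latentDim)

  gLayers <- G@layers
  dLayers <- D@layers
  vG <- NULL
  vD <- NULL
  ipe <- n %/% batch
  total <- as.integer(cfg@epochs) * ipe
  trace <- data.frame(iteration = seq_len(total), epoch = 0L, d_score = 0,
                      g_score = 0, d_loss = 0, d_real_loss = 0,
                      d_fake_loss = 0, g_loss = 0, supervised_loss = NA_real_)
  valRows <- list()

  with_seed(cfg@seed, {
    iter <- 0L
    for (epoch in seq_len(as.integer(cfg@epochs))) {
      perm <- sample.int(n)
      for (bi in seq_len(ipe)) {
        iter <- iter + 1L
        idx <- perm[((bi - 1L) * batch + 1L):(bi * batch)]
        real <- trainImages[, , , idx, drop = FALSE]
        labeled <- which(!unlabeledMask[idx])

        ## ---- discriminator step (generator fixed) ----
        z <- matrix(rnorm(latentDim * batch), latentDim, batch)
        gf <- net_forward_full(gLayers, z_input(z), training = TRUE)
        gLayers <- gf$layers
        fake <- gf$out

        dfR <- disc_logits(dLayers, real, training = TRUE)
        dLayers <- dfR$layers                  # running stats advance on real data
        dfF <- disc_logits(dLayers, fake, training = TRUE,
                           updateRunning = FALSE)
        probsR <- softmax_rows(dfR$logits)
        probsF <- softmax_rows(dfF$logits)
        pRealR <- 1 - probsR[, fakeIdx]
        pRealF <- 1 - probsF[, fakeIdx]

        dl <- discriminatorLoss(pRealR, pRealF, eps)
        supLoss <- NA_real_
        dlogitsR <- grad_not_fake(dfR$logits, fakeIdx, eps)
        if (length(labeled) > 0L) {
          supLoss <- supervisedLoss(
            rbind(probsR[labeled, , drop = FALSE]), labels1[idx][labeled], eps)
          gsup <- matrix(0, batch, fakeIdx)
          gsup[labeled, ] <- grad_ce(
            dfR$logits[labeled, , drop = FALSE], labels1[idx][labeled])
          dlogitsR <- dlogitsR + gsup
        }
        dlogitsF <- grad_ce(dfF$logits, rep(fakeIdx, batch))

        bwR <- net_backward_full(dLayers, dfR$caches,
                                 logits_to_map(dlogitsR))
        bwF <- net_backward_full(dLayers, dfF$caches,
                                 logits_to_map(dlogitsF))
        dGrads <- add_grads(grads_params(bwR$grads), grads_params(bwF$grads))
        sD <- sgdmUpdate(layers_params(dLayers), dGrads, vD,
                         cfg@learningRate, cfg@momentum)
        dLayers <- layers_set_params(dLayers, sD$weights)
        vD <- sD$velocity

        ## ---- generator step (discriminator fixed) ----
        # the fake batch from the D step is reused: G has not changed, so its
        # caches are still valid, but D has, so its forward pass is redone
        gf2 <- gf
        df2 <- disc_logits(dLayers, gf2$out, training = TRUE,
                           updateRunning = FALSE)
        pRealF2 <- 1 - softmax_rows(df2$logits)[, fakeIdx]
        gLoss <- generatorLoss(pRealF2, cfg@generatorLossForm, eps)
        dlogitsG <- if (cfg@generatorLossForm == "saturating") {
          grad_log_fake(df2$logits, fakeIdx)
        } else {
          grad_not_fake(df2$logits, fakeIdx, eps)
        }
        bwD <- net_backward_full(dLayers, df2$caches, logits_to_map(dlogitsG))
        bwG <- net_backward_full(gLayers, gf2$caches, bwD$dx)
        sG <- sgdmUpdate(layers_params(gLayers), grads_params(bwG$grads), vG,
                         cfg@learningRate, cfg@momentum)
        gLayers <- layers_set_params(gLayers, sG$weights)
        vG <- sG$velocity

        trace[iter, c("epoch", "d_score", "g_score", "d_loss", "d_real_loss",
                      "d_fake_loss", "g_loss", "supervised_loss")] <-
          list(epoch, mean(clip_range(pRealR, eps, 1 - eps)),
               mean(clip_range(pRealF, eps, 1 - eps)),
               dl[["dLoss"]], dl[["dRealLoss"]], dl[["dFakeLoss"]],
               gLoss, supLoss)

        if (!is.null(valImages) &&
            (iter %% as.integer(cfg@validationFrequency) == 0L ||
             iter == total)) {
          Dcur <- methods::new("DiscriminatorNet", layers = dLayers,
                               nClasses = D@nClasses)
          pred <- predictLesions(Dcur, valImages)
          valRows[[length(valRows) + 1L]] <-
            data.frame(iteration = iter, epoch = epoch,
                       accuracy = mean(pred$labels == valLabels))
        }
      }
    }
  })

  G@layers <- gLayers
  D@layers <- dLayers
  validation <- if (length(valRows) > 0L) {
    do.call(rbind, valRows)
  } else {
    data.frame(iteration = integer(0), epoch = integer(0),
               accuracy = numeric(0))
  }
  list(generator = G, discriminator = D,
       trace = new("TrainingTrace", iterations = trace,
                   validation = validation))
}

z_input <- function(z) {
  x <- array(0, c(1L, 1L, nrow(z), ncol(z)))
  x[1L, 1L, , ] <- z
  x
}

# head gradient matrix (n x units) -> (1, 1, units, n) map matching the
# discriminator's final conv output
logits_to_map <- function(dlogits) {
  array(t(dlogits), c(1L, 1L, ncol(dlogits), nrow(dlogits)))
}

#' Write a training trace as CSV
#'
#' One row per iteration with the score and loss columns; the companion
#' validation records go to `<path base>_validation.csv` when present.
#'
#' @param trace a [TrainingTrace-class].
#' @param path output CSV path.
#' @export
writeTrace <- function(trace, path) {
  write.csv(trace@iterations, path, row.names = FALSE)
  if (nrow(trace@validation) > 0L) {
    write.csv(trace@validation,
              sub("\\.csv$", "_validation.csv", path), row.names = FALSE)
  }
  invisible(path)
}
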