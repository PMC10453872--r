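# Synthetic two-class lesion dataset generator and the stratified 70/30 split.

METADATA_FIELDS <- c("image_name", "patient_id", "sex", "approx_age",
                     "anatomical_site", "diagnosis", "benign_malignant",
                     "target")

#' Draw one synthetic lesion image
#'
#' Renders a skin-toned background with one roughly elliptical lesion blob
#' whose border irregularity and color statistics are taken from the class's
#' parameters, plus hair-like dark streaks with the configured probability.
#' The border is an ellipse whose polar radius is modulated by a random
#' low-order Fourier series scaled by the class irregularity; within-lesion
#' color variegation is a mixture of smooth and per-pixel noise whose
#' standard deviation is the class color spread. Fully deterministic given
#' `(params, classLabel, seed)`.
#'
#' @param params a [SyntheticParams-class] object.
#' @param classLabel `"benign"` or `"malignant"`.
#' @param seed integer seed for this draw.
#' @return an RGB [ImageTensor-class] in \[0, 1\].
#' @examples
#' img <- makeLesionImage(SyntheticParams(imageSide = 32), "benign", seed = 7)
#' dim(img)
#' @export
makeLesionImage <- function(params, classLabel, seed = params@seed) {
  methods::validObject(params)
  if (!is.character(classLabel) ||
      !classLabel %in% c("benign", "malignant")) {
    stop("classLabel must be 'benign' or 'malignant'")
  }
  s <- as.integer(params@imageSide)
  irr <- params@lesionIrregularity[[classLabel]]
  cmean <- params@colorMeans[classLabel, ]
  cspread <- params@colorSpreads[classLabel, ]
  with_seed(seed, {
    # skin background: light tan plus a gentle illumination gradient and grain
    base <- c(0.86, 0.70, 0.62)
    ang <- runif(1, 0, 2 * pi)
    gx <- matrix(rep(seq(-0.5, 0.5, length.out = s), each = s), s, s)
    gy <- t(gx)
    grad <- 0.05 * (cos(ang) * gx + sin(ang) * gy)
    px <- array(0, c(s, s, 3L))
    for (c in 1:3) {
      px[, , c] <- base[c] + grad + matrix(rnorm(s * s, 0, 0.01), s, s)
    }

    # lesion blob: polar radius r(theta) modulated by a Fourier series
    cx <- s / 2 + runif(1, -0.05, 0.05) * s
    cy <- s / 2 + runif(1, -0.05, 0.05) * s
    r0 <- runif(1, 0.24, 0.30) * s
    aspect <- runif(1, 0.75, 1.0)
    ak <- rnorm(5, 0, 1) / (2:6)
    phik <- runif(5, 0, 2 * pi)
    xs <- matrix(rep(seq_len(s), each = s), s, s) - cx   # column index
    ys <- matrix(rep(seq_len(s), times = s), s, s) - cy  # row index
    theta <- atan2(ys, xs * aspect)
    dist <- sqrt((xs * aspect)^2 + ys^2)
    rtheta <- r0
    for (k in 1:5) rtheta <- rtheta + r0 * irr * ak[k] * cos((k + 1) * theta + phik[k])
    # soft 1.5-pixel edge
    mask <- clip_range((rtheta - dist) / 1.5 + 0.5, 0, 1)

    # lesion color: class mean + per-image shift + variegation at class spread
    shift <- rnorm(3, 0, cspread / 2)
    smoothn <- smooth_field(s, 4)
    for (c in 1:3) {
      field <- cmean[c] + shift[c] +
        cspread[c] * (0.7 * matrix(rnorm(s * s), s, s) + 0.7 * smoothn)
      px[, , c] <- (1 - mask) * px[, , c] + mask * field
    }

    # hair-like streaks
    if (params@hairProbability > 0 &&
        runif(1) < params@hairProbability) {
      nhair <- sample(1:4, 1)
      for (h in seq_len(nhair)) px <- draw_hair(px)
    }
    ImageTensor(clip_range(px, 0, 1), c(0, 1), "RGB")
  })
}

# low-frequency unit-variance-ish noise field: coarse grid, bilinear upsample
smooth_field <- function(s, cells) {
  g <- matrix(rnorm((cells + 1)^2), cells + 1, cells + 1)
  pos <- seq(1, cells + 1 - 1e-9, length.out = s)
  i0 <- floor(pos)
  fr <- pos - i0
  # bilinear in both axes
  rows <- g[i0, , drop = FALSE] * (1 - fr) + g[i0 + 1, , drop = FALSE] * fr
  rows[, i0, drop = FALSE] * rep(1 - fr, each = s) +
    rows[, i0 + 1, drop = FALSE] * rep(fr, each = s)
}

# paint one dark curved streak across the image
draw_hair <- function(px) {
  s <- dim(px)[1L]
  x0 <- runif(1, 1, s)
  y0 <- runif(1, 1, s)
  ang <- runif(1, 0, pi)
  len <- runif(1, 0.5, 1.2) * s
  curv <- rnorm(1, 0, 0.002)
  tt <- seq(0, len, by = 0.5)
  xs <- x0 + tt * cos(ang) + curv * tt^2
  ys <- y0 + tt * sin(ang)
  keep <- xs >= 1 & xs <= s & ys >= 1 & ys <= s
  xs <- round(xs[keep])
  ys <- round(ys[keep])
  if (length(xs) == 0L) return(px)
  hair_col <- c(0.10, 0.08, 0.06)
  alpha <- 0.8
  idx <- cbind(ys, xs)
  for (c in 1:3) {
    ch <- px[, , c]
    ch[idx] <- (1 - alpha) * ch[idx] + alpha * hair_col[c]
    px[, , c] <- ch
  }
  px
}

#' Generate a synthetic lesion dataset on disk
#'
#' Writes `nImages` PNG files plus one `metadata.csv` with the eight
#' standard ISIC-style columns (`image_name`, `patient_id`, `sex`,
#' `approx_age`, `anatomical_site`, `diagnosis`, `benign_malignant`,
#' `target`). The malignant fraction equals `classBalance` up to rounding and
#' `target == 1` exactly for malignant records. Unknown metadata fields are
#' emitted as empty strings.
#'
#' @param params a [SyntheticParams-class] object.
#' @param outDir output directory (created if missing).
#' @return invisibly, the data.frame of records (also written as CSV).
#' @export
makeDataset <- function(params, outDir) {
  methods::validObject(params)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  n <- as.integer(params@nImages)
  nMal <- as.integer(round_half_up(params@classBalance * n))
  classes <- rep("benign", n)
  if (nMal > 0L) {
    with_seed(child_seed(params@seed, 0L), {
      classes[sample.int(n, nMal)] <- "malignant"
    })
  }
  records <- with_seed(child_seed(params@seed, 1L), {
    sexes <- sample(c("male", "female", ""), n, replace = TRUE,
                    prob = c(0.45, 0.45, 0.1))
    ages <- ifelse(runif(n) < 0.05, NA_integer_,
                   sample(20:85, n, replace = TRUE))
    sites <- sample(c("torso", "lower extremity", "upper extremity",
                      "head/neck", ""), n, replace = TRUE,
                    prob = c(0.3, 0.25, 0.25, 0.15, 0.05))
    diag <- ifelse(classes == "malignant", "melanoma",
                   sample(c("nevus", "seborrheic keratosis"), n,
                          replace = TRUE))
    data.frame(
      image_name = sprintf("synimg_%05d", seq_len(n)),
      patient_id = sprintf("synpat_%05d", sample.int(n)),
      sex = sexes,
      approx_age = ages,
      anatomical_site = sites,
      diagnosis = diag,
      benign_malignant = classes,
      target = as.integer(classes == "malignant"),
      stringsAsFactors = FALSE)
  })
  for (i in seq_len(n)) {
    img <- makeLesionImage(params, classes[i], child_seed(params@seed, i + 1L))
    writePng(img, file.path(outDir, paste0(records$image_name[i], ".png")))
  }
  writeMetadata(records, file.path(outDir, "metadata.csv"))
  invisible(records)
}

#' Write metadata records as CSV
#'
#' Header is exactly the eight standard fields, comma-separated, UTF-8;
#' missing fields become empty strings.
#'
#' @param records data.frame of records.
#' @param path output CSV path.
#' @export
writeMetadata <- function(records, path) {
  stopifnot(all(METADATA_FIELDS %in% names(records)))
  out <- records[, METADATA_FIELDS]
  out$approx_age <- ifelse(is.na(out$approx_age), "", out$approx_age)
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a metadata CSV
#'
#' @param path CSV file with the eight standard columns.
#' @return data.frame with `approx_age` integer (`NA` when blank) and
#'   `target` integer.
#' @export
readMetadata <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", fileEncoding = "UTF-8")
  if (!identical(names(rec), METADATA_FIELDS)) {
    stop("metadata header must be exactly: ",
         paste(METADATA_FIELDS, collapse = ","))
  }
  rec$approx_age <- suppressWarnings(as.integer(rec$approx_age))
  rec$target <- as.integer(rec$target)
  if (anyDuplicated(rec$image_name)) stop("image_name values must be unique")
  if (!all(rec$target == as.integer(rec$benign_malignant == "malignant"))) {
    stop("target must be 1 exactly for malignant records")
  }
  rec
}

#' Stratified train/test split with per-class unlabeled masking
#'
#' The total training size is `round(trainFraction * n)`; it is allocated
#' across classes proportionally (largest-remainder rule), so each class's
#' share of the test set matches the global test fraction as closely as
#' integer counts allow. A seeded random `unlabeledFraction` of the training
#' records of each class is then marked unlabeled. Matches the published
#' 70/30 split arithmetic exactly on balanced counts.
#'
#' @param records data.frame with at least `image_name` and `target`.
#' @param trainFraction training fraction in (0, 1); default 0.7.
#' @param unlabeledFraction fraction of training records whose labels are
#'   withheld, in \[0, 1); default 0.3.
#' @param seed integer seed.
#' @return a [SplitResult-class] object.
#' @examples
#' rec <- data.frame(image_name = sprintf("im%02d", 1:10),
#'                   target = rep(0:1, each = 5))
#' splitDataset(rec, 0.7, 0.3, seed = 1)
#' @export
splitDataset <- function(records, trainFraction = 0.7,
                         unlabeledFraction = 0.3, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must lie in (0, 1)")
  }
  if (unlabeledFraction < 0 || unlabeledFraction >= 1) {
    stop("unlabeledFraction must lie in [0, 1)")
  }
  counts <- table(records$target)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("each class needs at least 2 records to split")
  }
  classes <- sort(unique(records$target))
  sizes <- vapply(classes, function(cl) sum(records$target == cl), integer(1))
  nTrainTotal <- as.integer(round_half_up(trainFraction * nrow(records)))
  # largest-remainder allocation of the training quota across classes
  exact <- trainFraction * sizes
  quota <- pmin(pmax(floor(exact), 1L), sizes - 1L)
  rem <- nTrainTotal - sum(quota)
  if (rem > 0L) {
    ord <- order(exact - floor(exact), decreasing = TRUE)
    for (i in ord) {
      if (rem == 0L) break
      if (quota[i] < sizes[i] - 1L) {
        quota[i] <- quota[i] + 1L
        rem <- rem - 1L
      }
    }
  }
  with_seed(seed, {
    trainIdx <- integer(0)
    unlabeled <- integer(0)
    for (ci in seq_along(classes)) {
      idx <- which(records$target == classes[ci])
      nTrain <- quota[ci]
      tr <- sort(sample(idx, nTrain))
      trainIdx <- c(trainIdx, tr)
      nUnl <- as.integer(round_half_up(unlabeledFraction * nTrain))
      if (nUnl > 0L) unlabeled <- c(unlabeled, sample(tr, nUnl))
    }
    trainIdx <- sort(trainIdx)
    testIdx <- setdiff(seq_len(nrow(records)), trainIdx)
    new("SplitResult",
        trainRecords = records[trainIdx, , drop = FALSE],
        testRecords = records[testIdx, , drop = FALSE],
        unlabeledMask = trainIdx %in% unlabeled)
  })
}
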