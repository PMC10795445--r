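## Joint-location regression. The backbone contract is: image in, six finite
## reals out ((row, col) for LeftCollar, RightCollar, Spine2). The default
## backbone is a small pooled-feature multilayer perceptron -- average-pool
## patches form the convolutional front end, one hidden ReLU layer the
## regressor -- trained with Adam on an MSE loss over coordinates normalized
## to [0, 1]. A purely linear backbone is also available.

poolFeatures <- function(P, poolSize) {
  H <- nrow(P); W <- ncol(P)
  gr <- ceiling(seq_len(H) * poolSize / H)
  gc <- ceiling(seq_len(W) * poolSize / W)
  s <- rowsum(t(rowsum(P, gr)), gc)          # poolSize x poolSize sums (t)
  cnt <- outer(tabulate(gc, poolSize), tabulate(gr, poolSize))
  as.vector(t(s / cnt))
}

datasetFeatures <- function(samples, poolSize) {
  t(vapply(samples, function(s) poolFeatures(s$image@pixels, poolSize),
           numeric(poolSize * poolSize)))
}

datasetTargets <- function(samples) {
  t(vapply(samples, function(s) {
    co <- s$label@coords[targetJointNames(), , drop = FALSE]
    sz <- s$label@imageSize
    as.vector(t(co / sz))                    # row/H, col/W per joint
  }, numeric(6)))
}

relu <- function(x) (x > 0) * x

forwardNet <- function(params, X, backbone) {
  if (backbone == "linear")
    return(sweep(X %*% params$W2, 2, params$b2, "+"))
  H1 <- relu(sweep(X %*% params$W1, 2, params$b1, "+"))
  sweep(H1 %*% params$W2, 2, params$b2, "+")
}

#' Train the joint-location regressor
#'
#' Minimizes the mean-squared error between predicted and true normalized
#' joint coordinates with the Adam optimizer, stopping after a fixed number
#' of epochs. Deterministic under a fixed seed. Records training and
#' validation loss per epoch.
#'
#' @param dataset a \code{SyntheticDataset} with a non-empty train split.
#' @param config list of hyperparameters; unset entries take the defaults
#'   \code{backbone = "pool_mlp"}, \code{poolSize = 20}, \code{hidden = 64},
#'   \code{lr = 1e-3}, \code{batchSize = 32}, \code{epochs = 200},
#'   \code{dropout = 0}, \code{seed = 0}, \code{lrSchedule = "cosine"}
#'   (cosine decay of the step size to zero over the epoch budget;
#'   \code{"constant"} disables it). The method's reference schedule is
#'   2000 epochs.
#' @return a \code{JointPredictor}.
#' @export
trainJointModel <- function(dataset, config = list()) {
  if (!is(dataset, "SyntheticDataset")) stopInvalid("dataset must be a SyntheticDataset")
  if (length(dataset@trainIdx) == 0) stopInvalid("train split is empty")
  cfg <- utils::modifyList(list(backbone = "pool_mlp", poolSize = 20L,
                                hidden = 64L, lr = 1e-3, batchSize = 32L,
                                epochs = 200L, dropout = 0, seed = 0L,
                                lrSchedule = "cosine"), config)
  if (!cfg$lrSchedule %in% c("cosine", "constant"))
    stopInvalid("lrSchedule must be 'cosine' or 'constant'")
  if (!cfg$backbone %in% c("pool_mlp", "linear"))
    stopInvalid("backbone must be 'pool_mlp' or 'linear'")
  sz <- dim(dataset@samples[[1]]$image@pixels)
  Xall <- datasetFeatures(dataset@samples, cfg$poolSize)
  Yall <- datasetTargets(dataset@samples)
  tr <- dataset@trainIdx; va <- dataset@validIdx
  mu <- colMeans(Xall[tr, , drop = FALSE])
  sd <- apply(Xall[tr, , drop = FALSE], 2, stats::sd)
  sd[!is.finite(sd)] <- 0
  ## floor the per-feature scale at a fraction of the typical scale:
  ## near-constant features otherwise standardize to huge values and
  ## destabilize the optimization
  floorSd <- if (any(sd > 0)) max(1e-8, 0.1 * stats::median(sd[sd > 0])) else 1
  sd <- pmax(sd, floorSd)
  Xall <- sweep(sweep(Xall, 2, mu), 2, sd, "/")
  Xtr <- Xall[tr, , drop = FALSE]; Ytr <- Yall[tr, , drop = FALSE]
  Xva <- Xall[va, , drop = FALSE]; Yva <- Yall[va, , drop = FALSE]
  nf <- ncol(Xtr); nh <- as.integer(cfg$hidden)

  params <- withSeed(cfg$seed, {
    if (cfg$backbone == "linear") {
      list(W2 = matrix(stats::rnorm(nf * 6, sd = sqrt(1 / nf)), nf, 6),
           b2 = rep(0.5, 6))
    } else {
      list(W1 = matrix(stats::rnorm(nf * nh, sd = sqrt(2 / nf)), nf, nh),
           b1 = rep(0, nh),
           W2 = matrix(stats::rnorm(nh * 6, sd = sqrt(1 / nh)), nh, 6),
           b2 = rep(0.5, 6))
    }
  })
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
  step <- 0
  ntr <- nrow(Xtr)
  trainLoss <- numeric(cfg$epochs); validLoss <- numeric(cfg$epochs)
  mseOf <- function(X, Y) mean((forwardNet(params, X, cfg$backbone) - Y)^2)

  for (ep in seq_len(cfg$epochs)) {
    lrEp <- if (cfg$lrSchedule == "cosine")
      cfg$lr * 0.5 * (1 + cos(pi * (ep - 1) / cfg$epochs)) else cfg$lr
    ord <- withSeed(deriveSeed(cfg$seed, ep, 7L), sample.int(ntr))
    for (b0 in seq(1, ntr, by = cfg$batchSize)) {
      idx <- ord[b0:min(b0 + cfg$batchSize - 1, ntr)]
      X <- Xtr[idx, , drop = FALSE]; Y <- Ytr[idx, , drop = FALSE]
      nb <- nrow(X)
      grads <- list()
      if (cfg$backbone == "linear") {
        Yh <- sweep(X %*% params$W2, 2, params$b2, "+")
        dY <- 2 * (Yh - Y) / (nb * 6)
        grads$W2 <- crossprod(X, dY)
        grads$b2 <- colSums(dY)
      } else {
        A1 <- sweep(X %*% params$W1, 2, params$b1, "+")
        H1 <- relu(A1)
        if (cfg$dropout > 0) {
          keep <- withSeed(deriveSeed(cfg$seed, step, 13L),
                           matrix(stats::runif(length(H1)) >= cfg$dropout,
                                  nrow(H1), ncol(H1)))
          H1 <- H1 * keep / (1 - cfg$dropout)
        }
        Yh <- sweep(H1 %*% params$W2, 2, params$b2, "+")
        dY <- 2 * (Yh - Y) / (nb * 6)
        grads$W2 <- crossprod(H1, dY)
        grads$b2 <- colSums(dY)
        dH <- dY %*% t(params$W2)
        if (cfg$dropout > 0) dH <- dH * keep / (1 - cfg$dropout)
        dA <- dH * (A1 > 0)
        grads$W1 <- crossprod(X, dA)
        grads$b1 <- colSums(dA)
      }
      step <- step + 1
      ## clip the global gradient norm (stabilizes occasional large
      ## minibatch gradients)
      gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
      if (is.finite(gnorm) && gnorm > 5)
        grads <- lapply(grads, function(g) g * (5 / gnorm))
      for (nm in names(grads)) {
        g <- grads[[nm]]
        m[[nm]] <- b1a * m[[nm]] + (1 - b1a) * g
        v[[nm]] <- b2a * v[[nm]] + (1 - b2a) * g^2
        mhat <- m[[nm]] / (1 - b1a^step)
        vhat <- v[[nm]] / (1 - b2a^step)
        params[[nm]] <- params[[nm]] - lrEp * mhat / (sqrt(vhat) + eps)
      }
    }
    trainLoss[ep] <- mseOf(Xtr, Ytr)
    validLoss[ep] <- if (nrow(Xva) > 0) mseOf(Xva, Yva) else NA_real_
    if (!is.finite(trainLoss[ep]))
      stop(errorCondition("training diverged: non-finite loss",
                          class = c("sgroi_training_diverged", "error", "condition")))
  }
  new("JointPredictor", backbone = cfg$backbone,
      params = c(params, list(featMean = mu, featSd = sd,
                              poolSize = as.integer(cfg$poolSize))),
      inputSize = as.integer(sz),
      trainMeta = list(epochs = as.integer(cfg$epochs),
                       trainLoss = trainLoss, validLoss = validLoss,
                       seed = as.integer(cfg$seed), config = cfg))
}

#' Predict joint locations on a coronal image
#'
#' Pure function of (model, image): returns the three target joints in pixel
#' coordinates of the input image.
#'
#' @param model a trained \code{JointPredictor}.
#' @param image a \code{CoronalImage} matching the model input size.
#' @return a \code{JointLabel2D}.
#' @export
predictJoints <- function(model, image) {
  if (!is(model, "JointPredictor")) stopInvalid("model must be a JointPredictor")
  if (!is(image, "CoronalImage")) stopInvalid("image must be a CoronalImage")
  sz <- dim(image@pixels)
  if (!identical(as.integer(sz), model@inputSize))
    stopInvalid(sprintf("image size %dx%d does not match model input %dx%d",
                        sz[1], sz[2], model@inputSize[1], model@inputSize[2]))
  x <- poolFeatures(image@pixels, model@params$poolSize)
  x <- (x - model@params$featMean) / model@params$featSd
  y <- forwardNet(model@params, matrix(x, 1), model@backbone)
  co <- matrix(y, 3, 2, byrow = TRUE,
               dimnames = list(targetJointNames(), c("row", "col")))
  co[, 1] <- pmin(pmax(co[, 1] * sz[1], 0.5), sz[1] + 0.5)
  co[, 2] <- pmin(pmax(co[, 2] * sz[2], 0.5), sz[2] + 0.5)
  new("JointLabel2D", coords = co, imageSize = as.integer(sz))
}

#' Mean per-joint position error
#'
#' Euclidean distance in mm between predicted and ground-truth joints
#' (pixel deltas scaled by the pixel spacing), plus per-axis statistics of
#' the absolute coordinate differences in the superior--inferior (row) and
#' left--right (column) directions.
#'
#' @param predictions,groundTruth lists of \code{JointLabel2D} (or single
#'   objects) of equal length with identical joint sets.
#' @param spacingMm (row, col) mm/pixel, or a list of such pairs per sample.
#' @return an object of class \code{MPJPEReport}: per-joint mean errors,
#'   overall mean/sd, per-axis mean/sd (all mm), and n.
#' @export
mpjpe <- function(predictions, groundTruth, spacingMm) {
  if (is(predictions, "JointLabel2D")) predictions <- list(predictions)
  if (is(groundTruth, "JointLabel2D")) groundTruth <- list(groundTruth)
  if (length(predictions) != length(groundTruth))
    stopInvalid("predictions and groundTruth must have equal length")
  n <- length(predictions)
  if (!is.list(spacingMm)) spacingMm <- rep(list(spacingMm), n)
  if (length(spacingMm) != n) stopInvalid("spacingMm must match sample count")
  per <- vector("list", n)
  for (i in seq_len(n)) {
    p <- predictions[[i]]@coords; g <- groundTruth[[i]]@coords
    if (!setequal(rownames(p), rownames(g)))
      stopInvalid("mismatched joint sets")
    g <- g[rownames(p), , drop = FALSE]
    sp <- spacingMm[[i]]
    dsi <- (p[, 1] - g[, 1]) * sp[1]
    dlr <- (p[, 2] - g[, 2]) * sp[2]
    per[[i]] <- cbind(si = dsi, lr = dlr, euc = sqrt(dsi^2 + dlr^2))
  }
  D <- do.call(rbind, per)
  jn <- rownames(per[[1]])
  perJoint <- vapply(jn, function(j) mean(D[rownames(D) == j, "euc"]), 0)
  structure(list(
    perJointMeanMm = perJoint,
    meanMm = mean(D[, "euc"]), sdMm = stats::sd(D[, "euc"]),
    siMeanMm = mean(abs(D[, "si"])), siSdMm = stats::sd(abs(D[, "si"])),
    lrMeanMm = mean(abs(D[, "lr"])), lrSdMm = stats::sd(abs(D[, "lr"])),
    n = n), class = "MPJPEReport")
}

#' @export
print.MPJPEReport <- function(x, ...) {
  cat(sprintf("MPJPE over %d samples: %.2f +/- %.2f mm\n", x$n, x$meanMm, x$sdMm))
  cat(sprintf("  S-I: %.2f +/- %.2f mm   L-R: %.2f +/- %.2f mm\n",
              x$siMeanMm, x$siSdMm, x$lrMeanMm, x$lrSdMm))
  for (j in names(x$perJointMeanMm))
    cat(sprintf("  %-12s %.2f mm\n", j, x$perJointMeanMm[j]))
  invisible(x)
}
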