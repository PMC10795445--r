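test_that("a constant-function dataset is fit to near-zero training error", {
  one <- makeDotSample(42)
  samples <- rep(list(one), 50)
  ds <- new("SyntheticDataset", samples = samples, trainIdx = 1:40,
            validIdx = 41:50, ratio = 0.8, seed = 0L)
  m <- trainJointModel(ds, list(epochs = 200, poolSize = 16, hidden = 32,
                                lr = 1e-2, seed = 2))
  finalLossPx2 <- tail(m@trainMeta$trainLoss, 1) * 64^2
  expect_lt(finalLossPx2, 0.01)
})

test_that("the affine dot toy set is learned below 2 px validation MPJPE", {
  ds <- makeDotDataset(n = 500, seed = 300)
  m <- trainJointModel(ds, toyTrainConfig(epochs = 200))
  rep <- dotValidationMpjpe(m, ds)
  expect_lt(rep$meanMm, 2)
  ## per-joint errors are also small
  expect_true(all(rep$perJointMeanMm < 3))
  ## validation loss decreased over training
  expect_lt(m@trainMeta$validLoss[200], m@trainMeta$validLoss[1])
})

test_that("prediction is a pure, size-checked function", {
  ds <- makeDotDataset(n = 60, seed = 40)
  m <- trainJointModel(ds, list(epochs = 20, poolSize = 16, hidden = 16,
                                seed = 3))
  img <- datasetSamples(ds)[[1]]$image
  p1 <- predictJoints(m, img)
  p2 <- predictJoints(m, img)
  expect_identical(labelCoords(p1), labelCoords(p2))
  expect_true(all(is.finite(labelCoords(p1))))
  wrong <- new("CoronalImage", pixels = matrix(0, 32, 32),
               pixelSpacingMm = c(1, 1), cropOriginMm = c(0, 0),
               sourceSeed = 0L)
  expect_error(predictJoints(m, wrong), class = "sgroi_invalid_input")
  expect_error(trainJointModel(new("SyntheticDataset", samples = list(),
                                   trainIdx = integer(), validIdx = integer(),
                                   ratio = 0.5, seed = 0L)),
               class = "sgroi_invalid_input")
})

test_that("MPJPE matches hand-computed geometry", {
  gt <- new("JointLabel2D",
            coords = matrix(c(10, 10, 20, 20, 30, 30), 3, 2, byrow = TRUE,
                            dimnames = list(c("LeftCollar", "RightCollar",
                                              "Spine2"), c("row", "col"))),
            imageSize = c(64L, 64L))
  same <- mpjpe(gt, gt, c(1, 1))
  expect_equal(same$meanMm, 0)
  expect_equal(unname(same$perJointMeanMm), c(0, 0, 0))
  ## 3-4-5 offset at 1 mm/px
  co <- labelCoords(gt); co[, 1] <- co[, 1] + 3; co[, 2] <- co[, 2] + 4
  off <- new("JointLabel2D", coords = co, imageSize = c(64L, 64L))
  r <- mpjpe(off, gt, c(1, 1))
  expect_equal(r$meanMm, 5)
  expect_equal(r$siMeanMm, 3)
  expect_equal(r$lrMeanMm, 4)
  ## spacing scales errors to mm
  r2 <- mpjpe(off, gt, c(2, 2))
  expect_equal(r2$meanMm, 10)
  ## Euclidean mean dominates each per-axis mean
  expect_gte(r$meanMm, r$siMeanMm)
  expect_gte(r$meanMm, r$lrMeanMm)
})

test_that("MPJPE of Gaussian offsets matches the half-normal mean", {
  sigma <- 3
  set.seed(11)
  n <- 2000
  labs <- lapply(seq_len(n), function(i) {
    co <- matrix(32, 3, 2, dimnames = list(c("LeftCollar", "RightCollar",
                                             "Spine2"), c("row", "col")))
    new("JointLabel2D", coords = co, imageSize = c(64L, 64L))
  })
  preds <- lapply(labs, function(l) {
    co <- labelCoords(l) + matrix(rnorm(6, 0, sigma), 3, 2)
    co[] <- pmin(pmax(co, 0.5), 64.5)
    new("JointLabel2D", coords = co, imageSize = c(64L, 64L))
  })
  r <- mpjpe(preds, labs, c(1, 1))
  expect_equal(r$siMeanMm, sigma * sqrt(2 / pi), tolerance = 0.05)
  expect_equal(r$lrMeanMm, sigma * sqrt(2 / pi), tolerance = 0.05)
})

test_that("MPJPE is translation-equivariant", {
  ds <- makeDotDataset(n = 10, seed = 77)
  gts <- lapply(datasetSamples(ds), `[[`, "label")
  shift <- function(l, dr, dc) {
    co <- labelCoords(l); co[, 1] <- co[, 1] + dr; co[, 2] <- co[, 2] + dc
    new("JointLabel2D", coords = co, imageSize = l@imageSize)
  }
  preds <- lapply(gts, shift, dr = 1.5, dc = -2)
  r1 <- mpjpe(preds, gts, c(1, 1))
  r2 <- mpjpe(lapply(preds, shift, dr = 3, dc = 3),
              lapply(gts, shift, dr = 3, dc = 3), c(1, 1))
  expect_equal(r1$meanMm, r2$meanMm)
  expect_equal(r1$siMeanMm, r2$siMeanMm)
})

test_that("checkpoints round-trip through JSON exactly", {
  ds <- makeDotDataset(n = 40, seed = 55)
  m <- trainJointModel(ds, list(epochs = 10, poolSize = 8, hidden = 8,
                                seed = 4))
  path <- tempfile(fileext = ".json")
  saveJointModel(m, path)
  m2 <- readJointModel(path)
  img <- datasetSamples(ds)[[3]]$image
  expect_equal(labelCoords(predictJoints(m2, img)),
               labelCoords(predictJoints(m, img)), tolerance = 1e-12)
})
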