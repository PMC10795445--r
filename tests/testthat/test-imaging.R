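test_that("a cube projects to a filled square silhouette", {
  b <- boxBody(100)
  pc <- projectCoronal(b, spacingMm = 1, marginMm = 5)
  on <- pixels(pc$image) > 0
  ## ~100 x 100 mm of silhouette at 1 mm/px
  expect_equal(sum(on), 100 * 100, tolerance = 0.03)
  rows <- range(which(rowSums(on) > 0)); cols <- range(which(colSums(on) > 0))
  expect_equal(diff(rows) + 1, 100, tolerance = 0.03)
  expect_equal(diff(cols) + 1, 100, tolerance = 0.03)
  expect_error(projectCoronal(new("BodyModel", vertices = b@vertices,
                                  faces = b@faces[0, , drop = FALSE],
                                  joints = b@joints, shapeSeed = 0L,
                                  heightMm = 100)),
               class = "sgroi_invalid_input")
})

test_that("patient left lands at the larger column index", {
  b <- sampleBody(shapeParams())
  pc <- projectCoronal(b)
  expect_gt(pc$joints2d["LeftCollar", "col"], pc$joints2d["RightCollar", "col"])
  ## superior joints have smaller row indices
  expect_lt(pc$joints2d["Head", "row"], pc$joints2d["Spine2", "row"])
})

test_that("anterior translation does not change silhouette membership", {
  b <- sampleBody(shapeParams())
  bShift <- new("BodyModel",
                vertices = sweep(vertices(b), 2, c(0, 50, 0), "+"),
                faces = faces(b),
                joints = sweep(joints(b), 2, c(0, 50, 0), "+"),
                shapeSeed = 0L, heightMm = heightMm(b))
  m1 <- pixels(projectCoronal(b)$image) > 0
  m2 <- pixels(projectCoronal(bShift)$image) > 0
  expect_identical(m1, m2)
})

test_that("torso crop keeps the targets, transforms labels exactly", {
  b <- scaleToHeight(sampleBody(shapeParams()), 1617)
  pc <- projectCoronal(b)
  cr <- cropTorso(pc$image, pc$joints2d, size = 200, seed = 5)
  lab <- labelCoords(cr$label)
  ## anatomy: Spine2 inferior to the collars
  expect_gt(lab["Spine2", "row"], lab["LeftCollar", "row"])
  ## labels land on body pixels
  for (j in rownames(lab)) {
    r <- round(lab[j, "row"]); c <- round(lab[j, "col"])
    expect_gt(pixels(cr$image)[r, c], 0)
  }
  ## round-trip: label -> mm equals the true joint position within 0.5 px
  sp <- pixelSpacing(cr$image); org <- cropOrigin(cr$image)
  for (j in rownames(lab)) {
    x <- org[1] + (lab[j, "col"] - 1) * sp[2]
    z <- org[2] - (lab[j, "row"] - 1) * sp[1]
    expect_lt(abs(x - joints(b)[j, "x"]), 0.5 * sp[2])
    expect_lt(abs(z - joints(b)[j, "z"]), 0.5 * sp[1])
  }
  ## spacing consistent with the crop extent
  expect_equal(sp[1], sp[2])
  expect_equal(nrow(pixels(cr$image)), 200)
})

test_that("joint positions in mm agree across crop resolutions", {
  b <- scaleToHeight(sampleBody(shapeParams()), 1617)
  pc <- projectCoronal(b)
  mmOf <- function(size) {
    cr <- cropTorso(pc$image, pc$joints2d, size = size, seed = 9)
    lab <- labelCoords(cr$label)
    sp <- pixelSpacing(cr$image); org <- cropOrigin(cr$image)
    cbind(x = org[1] + (lab[, "col"] - 1) * sp[2],
          z = org[2] - (lab[, "row"] - 1) * sp[1])
  }
  coarse <- mmOf(100); coarseSp <- NULL
  crC <- cropTorso(pc$image, pc$joints2d, size = 100, seed = 9)
  tol <- pixelSpacing(crC$image)[1]  # one pixel of the coarsest grid
  for (size in c(200, 400)) {
    fine <- mmOf(size)
    expect_lt(max(abs(fine - coarse)), tol)
  }
})

test_that("dataset assembly sizes, splits and determinism", {
  ds <- buildDataset(12, ratio = 0.85, seed = 4, size = 64,
                     projectionSpacingMm = 4)
  expect_length(datasetSamples(ds), 12)
  expect_length(trainIndices(ds), round(0.85 * 12))
  expect_length(intersect(trainIndices(ds), validIndices(ds)), 0)
  expect_setequal(c(trainIndices(ds), validIndices(ds)), 1:12)

  ds2 <- buildDataset(2, ratio = 0.5, seed = 1, size = 48,
                      projectionSpacingMm = 4)
  expect_length(trainIndices(ds2), 1)
  expect_length(validIndices(ds2), 1)

  ds3 <- buildDataset(2, ratio = 0.5, seed = 1, size = 48,
                      projectionSpacingMm = 4)
  expect_identical(trainIndices(ds2), trainIndices(ds3))
  expect_identical(pixels(datasetSamples(ds2)[[1]]$image),
                   pixels(datasetSamples(ds3)[[1]]$image))

  expect_error(buildDataset(1, seed = 1), class = "sgroi_invalid_input")
  expect_error(buildDataset(10, ratio = 1, seed = 1),
               class = "sgroi_invalid_input")
})

test_that("background is exactly zero and body pixels positive", {
  ds <- buildDataset(3, ratio = 0.5, seed = 6, size = 64,
                     projectionSpacingMm = 4)
  for (s in datasetSamples(ds)) {
    p <- pixels(s$image)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(sum(p == 0), 0)
    expect_gt(sum(p > 0), 0)
  }
})
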