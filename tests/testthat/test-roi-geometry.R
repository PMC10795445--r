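test_that("S-I bounds from joints apply the configured shifts", {
  j <- phantomJoints(collarZ = 1400, spine2Z = 1150)
  b <- siBoundsFromJoints(j, shiftConfig())
  expect_equal(unname(b), c(1410, 1120))
  ## zero shifts return the joint coordinates themselves
  b0 <- siBoundsFromJoints(j, shiftConfig(upperShiftMm = 0, lowerShiftMm = 0))
  expect_equal(unname(b0), c(1400, 1150))
  ## translation equivariance
  j2 <- j; j2[, "z"] <- j2[, "z"] + 37.5
  expect_equal(unname(siBoundsFromJoints(j2, shiftConfig())),
               unname(b) + 37.5)
  ## asymmetric collars are averaged
  j3 <- j; j3["LeftCollar", "z"] <- 1404; j3["RightCollar", "z"] <- 1396
  expect_equal(unname(siBoundsFromJoints(j3, shiftConfig())[1]), 1410)
  ## degenerate geometry
  expect_error(siBoundsFromJoints(phantomJoints(collarZ = 1150, spine2Z = 1400),
                                  shiftConfig()),
               class = "sgroi_degenerate_geometry")
})

test_that("S-I bounds from the breast contour apply per-category extensions", {
  be <- breastContourSpec(1300, 1150, "left", "breast_eval")
  expect_equal(unname(siBoundsFromBreast(be, shiftConfig())), c(1327, 1138))
  ptv <- breastContourSpec(1350, 1150, "left", "PTV")
  expect_equal(unname(siBoundsFromBreast(ptv, shiftConfig())), c(1326, 1133))
  zero <- shiftConfig(breastEvalSupMm = 0, breastEvalInfMm = 0)
  expect_equal(unname(siBoundsFromBreast(be, zero)), c(1300, 1150))
  ## PTV-style negative superior extension can degenerate a short contour
  shallow <- breastContourSpec(1155, 1150, "left", "PTV")
  expect_error(siBoundsFromBreast(shallow, shiftConfig()),
               class = "sgroi_degenerate_geometry")
})

test_that("chest width measures the silhouette at the midline row", {
  sil <- rectSilhouette(widthMm = 300)
  cw <- chestWidth(sil, 1500, 1100, "left")
  expect_equal(cw$widthMm, 300)
  expect_equal(cw$ipsiEdgeX, 150)
  expect_equal(cw$contraEdgeX, -150)
  ## right laterality swaps the anchoring edge
  cwR <- chestWidth(sil, 1500, 1100, "right")
  expect_equal(cwR$ipsiEdgeX, -150)
  ## trapezoid: analytic width at the mid row
  trap <- trapezoidSilhouette(wBot = 200, wTop = 400, z0 = 1000, z1 = 1600)
  u <- 1500; l <- 1100; midZ <- (u + l) / 2
  analytic <- 200 + (400 - 200) * (midZ - 1000) / 600
  cwT <- chestWidth(trap, u, l)
  expect_equal(cwT$widthMm, analytic, tolerance = 2 / analytic)
  ## oracle: pixel count times spacing
  r <- round((trap@originMm[2] - midZ) / trap@spacingMm[1] + 1)
  expect_equal(cwT$widthMm, sum(trap@mask[r, ]) * trap@spacingMm[2])
  ## midline outside the silhouette
  expect_error(chestWidth(sil, 2500, 2100), class = "sgroi_degenerate_geometry")
})

test_that("ROI assembly: 3/4 width span and 80 mm chamfer", {
  sil <- rectSilhouette(widthMm = 320)
  cw <- chestWidth(sil, 1450, 1150, "left")
  roi <- buildRoi(1450, 1150, cw, "left", shiftConfig())
  lm <- roiLandmarks(roi)
  expect_equal(abs(lm$ipsiX - lm$contraX), 240)       # 3/4 of 320
  expect_equal(nrow(roiPolygon(roi)), 5)
  ## chamfer points at the retraction distance from the corner
  corner <- c(lm$ipsiX, lm$upperZ)
  d <- sqrt(colSums((t(lm$chamfer) - corner)^2))
  expect_equal(unname(d), c(80, 80))
  ## area = rectangle minus the cut triangle
  rectArea <- 240 * 300
  expect_equal(sgroi:::polygonArea(roiPolygon(roi)), rectArea - 80^2 / 2)
  ## no retraction: plain rectangle
  r0 <- buildRoi(1450, 1150, cw, "left", shiftConfig(retractionMm = 0))
  expect_equal(nrow(roiPolygon(r0)), 4)
  expect_equal(sgroi:::polygonArea(roiPolygon(r0)), rectArea)
})

test_that("oversized retraction falls back to the rectangle with a warning", {
  sil <- rectSilhouette(widthMm = 320)
  cw <- chestWidth(sil, 1250, 1150, "left")   # ROI only 100 mm tall
  expect_warning(roi <- buildRoi(1250, 1150, cw, "left",
                                 shiftConfig(retractionMm = 120)),
                 "retraction")
  expect_equal(nrow(roiPolygon(roi)), 4)
})

test_that("rasterization agrees with shoelace area and the pixel oracle", {
  square <- roiFromPolygon(cbind(x = c(0, 100, 100, 0),
                                 z = c(1100, 1100, 1200, 1200)))
  g <- roiGrid(square, spacingMm = 1)
  m <- rasterizeRoi(square, g)
  expect_equal(sum(maskMatrix(m)), 10000)
  ## chamfered default ROI: mask area within 1% of polygon area at 1 mm
  sil <- rectSilhouette(widthMm = 320)
  cw <- chestWidth(sil, 1450, 1150, "left")
  roi <- buildRoi(1450, 1150, cw, "left", shiftConfig())
  mm <- rasterizeRoi(roi, roiGrid(roi, spacingMm = 1))
  expect_equal(sum(maskMatrix(mm)), sgroi:::polygonArea(roiPolygon(roi)),
               tolerance = 0.01)
  ## exact oracle equivalence on random polygons
  for (seed in 1:8) {
    poly <- randomPolygon(seed)
    roiR <- roiFromPolygon(poly)
    g <- roiGrid(roiR, spacingMm = 2)
    expect_identical(maskMatrix(rasterizeRoi(roiR, g)), bruteMask(poly, g))
  }
  ## grid not covering the polygon
  tiny <- list(originMm = c(0, 1205), spacingMm = c(1, 1), dim = c(10L, 10L))
  expect_error(rasterizeRoi(square, tiny), class = "sgroi_invalid_input")
})

test_that("laterality flip mirrors the ROI exactly on a symmetric grid", {
  sil <- rectSilhouette(widthMm = 300)        # symmetric about x = 0
  jL <- phantomJoints()
  roiL <- generateAroiBody(sil, jL, "left", shiftConfig())
  roiR <- generateAroiBody(sil, jL, "right", shiftConfig())
  lmL <- roiLandmarks(roiL); lmR <- roiLandmarks(roiR)
  expect_identical(lmR$ipsiX, -lmL$ipsiX)
  expect_identical(lmR$contraX, -lmL$contraX)
  expect_identical(lmR$upperZ, lmL$upperZ)
  polyMirror <- roiPolygon(roiL); polyMirror[, 1] <- -polyMirror[, 1]
  ord <- function(p) { p <- p[order(p[, 1], p[, 2]), ]; dimnames(p) <- NULL; p }
  expect_identical(ord(polyMirror), ord(roiPolygon(roiR)))
  ## rasterized on a symmetric grid, the masks are column-reversed copies
  g <- list(originMm = c(-200, 1500), spacingMm = c(1, 1), dim = c(450L, 401L))
  mL <- maskMatrix(rasterizeRoi(roiL, g))
  mR <- maskMatrix(rasterizeRoi(roiR, g))
  expect_identical(mR, mL[, rev(seq_len(ncol(mL)))])
})

test_that("ROI area responds monotonically to shifts and retraction", {
  sil <- rectSilhouette(widthMm = 300)
  j <- phantomJoints()
  areaOf <- function(cfg) sgroi:::polygonArea(
    roiPolygon(generateAroiBody(sil, j, "left", cfg)))
  a1 <- areaOf(shiftConfig(upperShiftMm = 5))
  a2 <- areaOf(shiftConfig(upperShiftMm = 15))
  a3 <- areaOf(shiftConfig(upperShiftMm = 25))
  expect_true(a1 < a2 && a2 < a3)
  r1 <- areaOf(shiftConfig(retractionMm = 40))
  r2 <- areaOf(shiftConfig(retractionMm = 80))
  expect_gt(r1, r2)
})

test_that("stored landmarks re-derive the polygon bit-identically", {
  sil <- rectSilhouette(widthMm = 320)
  roi <- generateAroiBody(sil, phantomJoints(), "left", shiftConfig())
  lm <- roiLandmarks(roi)
  rebuilt <- sgroi:::roiFromBounds(lm$upperZ, lm$lowerZ, lm$ipsiX, lm$contraX,
                                   laterality(roi), shiftConfig(), "body")
  expect_identical(roiPolygon(rebuilt), roiPolygon(roi))
})

test_that("breast-driven ROI takes laterality from the contour", {
  sil <- rectSilhouette(widthMm = 300)
  ct <- breastContourSpec(1300, 1150, "right", "breast_eval")
  roi <- generateAroiBreast(sil, ct, shiftConfig())
  expect_identical(provenance(roi), "breast")
  expect_identical(laterality(roi), "right")
  lm <- roiLandmarks(roi)
  expect_equal(lm$upperZ, 1327)
  expect_equal(lm$lowerZ, 1138)
  expect_equal(lm$ipsiX, -150)
})

test_that("the model-prediction path produces a body ROI", {
  ds <- makeDotDataset(n = 40, seed = 21)
  m <- trainJointModel(ds, list(epochs = 5, poolSize = 8, hidden = 8, seed = 1))
  ## a 64 px crop of a synthetic body, silhouette from the same body
  b <- scaleToHeight(sampleBody(shapeParams()), 1617)
  pc <- projectCoronal(b)
  cr <- cropTorso(pc$image, pc$joints2d, size = 64, seed = 2)
  sil <- silhouetteFromBody(b)
  ## an untrained model may predict a short ROI, triggering the documented
  ## chamfer fallback warning
  roi <- suppressWarnings(
    generateAroiBody(sil, joints = NULL, laterality = "left",
                     cfg = shiftConfig(), model = m, image = cr$image))
  expect_s4_class(roi, "ROIRegion")
  expect_identical(provenance(roi), "body")
})
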