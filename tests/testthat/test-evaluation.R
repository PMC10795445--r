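maskOn <- function(rows, cols, dim = c(20L, 20L)) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[rows, cols] <- TRUE
  new("CoronalMask", mask = m, spacingMm = c(1, 1), originMm = c(0, 100))
}

test_that("DSC matches hand-counted overlaps and its identities", {
  a <- maskOn(1:10, 1:10)
  expect_equal(dsc(a, a)$dsc, 1)
  b <- maskOn(11:20, 11:20)
  expect_equal(dsc(a, b)$dsc, 0)
  ## two 10x10 squares overlapping in a 5x10 strip
  c2 <- maskOn(1:10, 6:15)
  r <- dsc(a, c2)
  expect_equal(r$dsc, 0.5)
  expect_equal(r$intersection, 50)
  ## symmetry
  expect_equal(dsc(c2, a)$dsc, r$dsc)
  ## empty masks are defined as DSC 1 with a warning
  e <- maskOn(integer(), integer())
  expect_warning(re <- dsc(e, e), "empty")
  expect_equal(re$dsc, 1)
  ## mismatched grids are rejected
  off <- new("CoronalMask", mask = a@mask, spacingMm = c(1, 1),
             originMm = c(5, 100))
  expect_error(dsc(a, off), class = "sgroi_invalid_input")
})

test_that("DSC equals the brute-force pixel count on random polygon pairs", {
  for (seed in 1:12) {
    p1 <- randomPolygon(seed)
    p2 <- randomPolygon(seed + 500)
    r1 <- roiFromPolygon(p1); r2 <- roiFromPolygon(p2)
    g <- roiGrid(r1, r2, spacingMm = 2)
    mA <- rasterizeRoi(r1, g); mB <- rasterizeRoi(r2, g)
    v <- dsc(mA, mB)$dsc
    expect_equal(v, bruteDsc(maskMatrix(mA), maskMatrix(mB)))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("DSC grows monotonically as a nested mask dilates toward the other", {
  target <- maskOn(5:16, 5:16)
  vals <- sapply(1:6, function(k) dsc(maskOn(10:(9 + k), 10:(9 + k)), target)$dsc)
  expect_true(all(diff(vals) > 0))
})

test_that("tuning recovers the true shifts from noise-free references", {
  co <- makeCohort(4, noiseSdMm = 0, seed = 31)
  res <- tuneShifts(co, candidates = c(0, 10, 20, 30, 40))
  expect_equal(unname(res$best), c(10, 30))
  expect_equal(max(res$dscGrid), 1)
  expect_equal(res$nCases, 4)
  ## a single candidate is returned as the argmax
  one <- tuneShifts(co[1], candidates = 15)
  expect_equal(unname(one$best), c(15, 15))
  expect_error(tuneShifts(list(), candidates = 5), class = "sgroi_invalid_input")
  expect_error(tuneShifts(co, candidates = numeric()),
               class = "sgroi_invalid_input")
})

test_that("tuning ties break toward the smallest candidate pair", {
  ## references identical for all candidates: a case whose clinical ROI is
  ## disjoint in no candidate -- use equal-DSC degenerate candidate list
  co <- makeCohort(2, noiseSdMm = 0, seed = 17)
  res <- tuneShifts(co, candidates = c(10, 10))
  expect_equal(unname(res$best), c(10, 10))
})

test_that("default candidate grid is 0 to 45 mm in 5 mm steps", {
  expect_equal(eval(formals(tuneShifts)$candidates), seq(0, 45, 5))
  expect_length(eval(formals(tuneShifts)$candidates), 10)
})

test_that("boundary distances recover the construction extensions", {
  co <- makeCohort(6, noiseSdMm = 0, seed = 23,
                   categoryMix = c(breast_eval = 4, PTV = 2))
  d <- meanBoundaryDistance(lapply(co, clinicalRoi), lapply(co, breastContour))
  expect_equal(unname(d$breast_eval[c("superiorMm", "inferiorMm")]), c(27, 12))
  expect_equal(unname(d$PTV[c("superiorMm", "inferiorMm")]), c(-24, 17))
  ## ROI boundaries equal to the contour boundaries give zero distances
  roi <- clinicalRoi(co[[1]])
  ct <- breastContourSpec(roiLandmarks(roi)$upperZ, roiLandmarks(roi)$lowerZ,
                          "left", "breast_eval")
  expect_warning(z <- meanBoundaryDistance(list(roi), list(ct)), "PTV")
  expect_equal(unname(z$breast_eval[c("superiorMm", "inferiorMm")]), c(0, 0))
})
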