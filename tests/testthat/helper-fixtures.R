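## Shared fixtures: all built in code at test time.

## Minimal valid BodyModel around an axis-aligned box (for projection tests).
boxBody <- function(sideMm = 100, center = c(0, 0, 1000)) {
  h <- sideMm / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, center, "+")
  f <- rbind(c(1, 2, 4), c(1, 4, 3), c(5, 8, 6), c(5, 7, 8),
             c(1, 5, 6), c(1, 6, 2), c(3, 4, 8), c(3, 8, 7),
             c(1, 3, 7), c(1, 7, 5), c(2, 6, 8), c(2, 8, 4))
  storage.mode(f) <- "integer"
  jnames <- c("Head", "Nose", "LeftCollar", "RightCollar", "Spine1",
              "Spine2", "LeftShoulder", "RightShoulder")
  j <- matrix(rep(center, each = length(jnames)), ncol = 3,
              dimnames = list(jnames, c("x", "y", "z")))
  new("BodyModel", vertices = v, faces = f, joints = j,
      shapeSeed = 0L, heightMm = sideMm)
}

## Rectangular silhouette phantom: full width widthMm centered on x = 0,
## z from z0 to z1, 1 mm/px by default.
rectSilhouette <- function(widthMm = 300, z0 = 1000, z1 = 1600,
                           spacingMm = 1, padMm = 50) {
  nc <- round((widthMm + 2 * padMm) / spacingMm)
  nr <- round((z1 - z0 + 2 * padMm) / spacingMm)
  origin <- c(-widthMm / 2 - padMm + spacingMm / 2,
              z1 + padMm - spacingMm / 2)
  xs <- origin[1] + (seq_len(nc) - 1) * spacingMm
  zs <- origin[2] - (seq_len(nr) - 1) * spacingMm
  mask <- outer(zs >= z0 & zs <= z1, abs(xs) <= widthMm / 2, FUN = "&")
  new("BodySilhouette", mask = mask, spacingMm = c(spacingMm, spacingMm),
      originMm = origin)
}

## Trapezoid phantom: half-width varies linearly from wBot/2 at z0 to
## wTop/2 at z1.
trapezoidSilhouette <- function(wBot = 200, wTop = 400, z0 = 1000, z1 = 1600,
                                spacingMm = 1, padMm = 50) {
  wmax <- max(wBot, wTop)
  nc <- round((wmax + 2 * padMm) / spacingMm)
  nr <- round((z1 - z0 + 2 * padMm) / spacingMm)
  origin <- c(-wmax / 2 - padMm + spacingMm / 2, z1 + padMm - spacingMm / 2)
  xs <- origin[1] + (seq_len(nc) - 1) * spacingMm
  zs <- origin[2] - (seq_len(nr) - 1) * spacingMm
  halfw <- function(z) (wBot + (wTop - wBot) * (z - z0) / (z1 - z0)) / 2
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    if (zs[i] >= z0 && zs[i] <= z1) mask[i, ] <- abs(xs) <= halfw(zs[i])
  }
  new("BodySilhouette", mask = mask, spacingMm = c(spacingMm, spacingMm),
      originMm = origin)
}

## Joint skeleton with the three targets at given z's, symmetric in x.
phantomJoints <- function(collarZ = 1400, spine2Z = 1150, collarX = 70) {
  j <- rbind(LeftCollar = c(collarX, 0, collarZ),
             RightCollar = c(-collarX, 0, collarZ),
             Spine2 = c(0, 0, spine2Z))
  colnames(j) <- c("x", "y", "z")
  j
}

## Independent even-odd point-in-polygon, written against the definition:
## a point strictly inside by crossing parity, or lying on the boundary,
## is in.
pipOracle <- function(px, pz, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    cr <- (poly[i, 1] - poly[j, 1]) * (pz - poly[j, 2]) -
      (px - poly[j, 1]) * (poly[i, 2] - poly[j, 2])
    if (abs(cr) <= 1e-9 &&
        px >= min(poly[c(i, j), 1]) - 1e-9 &&
        px <= max(poly[c(i, j), 1]) + 1e-9 &&
        pz >= min(poly[c(i, j), 2]) - 1e-9 &&
        pz <= max(poly[c(i, j), 2]) + 1e-9) return(TRUE)
    if ((poly[i, 2] > pz) != (poly[j, 2] > pz)) {
      xint <- poly[j, 1] + (poly[i, 1] - poly[j, 1]) *
        (pz - poly[j, 2]) / (poly[i, 2] - poly[j, 2])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

## Brute-force rasterization via the oracle, pixel by pixel.
bruteMask <- function(poly, grid) {
  m <- matrix(FALSE, grid$dim[1], grid$dim[2])
  for (r in seq_len(grid$dim[1])) {
    zc <- grid$originMm[2] - (r - 1) * grid$spacingMm[1]
    for (c in seq_len(grid$dim[2])) {
      xc <- grid$originMm[1] + (c - 1) * grid$spacingMm[2]
      m[r, c] <- pipOracle(xc, zc, poly)
    }
  }
  m
}

## Brute-force Dice from the definition, explicit pixel loop.
bruteDsc <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (r in seq_len(nrow(a))) for (c in seq_len(ncol(a))) {
    if (a[r, c] && b[r, c]) inter <- inter + 1
    if (a[r, c]) na <- na + 1
    if (b[r, c]) nb <- nb + 1
  }
  if (na + nb == 0) 1 else 2 * inter / (na + nb)
}

## Random simple (convex) polygon in a 120 x 120 mm window.
randomPolygon <- function(seed) {
  set.seed(seed)
  nv <- sample(3:7, 1)
  ang <- sort(runif(nv, 0, 2 * pi))
  rad <- runif(nv, 15, 55)
  cx <- runif(1, -20, 20); cz <- runif(1, 1180, 1220)
  cbind(x = cx + rad * cos(ang), z = cz + rad * sin(ang))
}

roiFromPolygon <- function(poly, laterality = "left", provenance = "body") {
  new("ROIRegion", polygon = poly, laterality = laterality,
      provenance = provenance,
      landmarks = list(upperZ = max(poly[, 2]), lowerZ = min(poly[, 2]),
                       ipsiX = max(poly[, 1]), contraX = min(poly[, 1]),
                       chamfer = NULL))
}

## Affine-labelled dot toy set: a Gaussian dot whose position determines the
## three joint labels through fixed affine maps.
makeDotSample <- function(seed, size = 64L, rad = 6) {
  set.seed(seed)
  r <- runif(1, 12, size - 12); c <- runif(1, 12, size - 12)
  px <- matrix(0, size, size)
  ii <- outer(seq_len(size), rep(1, size)); jj <- t(ii)
  d2 <- (ii - r)^2 + (jj - c)^2
  sel <- d2 < rad^2
  px[sel] <- exp(-d2[sel] / (rad^2 / 2))
  co <- rbind(LeftCollar = c(0.5 * r + 10, 0.5 * c + 8),
              RightCollar = c(0.3 * r + 20, 0.8 * c + 5),
              Spine2 = c(0.9 * r + 3, 0.2 * c + 30))
  colnames(co) <- c("row", "col")
  list(image = new("CoronalImage", pixels = px, pixelSpacingMm = c(1, 1),
                   cropOriginMm = c(0, 0), sourceSeed = as.integer(seed)),
       label = new("JointLabel2D", coords = co,
                   imageSize = c(size, size)))
}

makeDotDataset <- function(n = 500, seed = 100, size = 64L) {
  samples <- lapply(seq_len(n), function(i) makeDotSample(seed + i, size))
  ntr <- round(0.85 * n)
  new("SyntheticDataset", samples = samples, trainIdx = seq_len(ntr),
      validIdx = seq.int(ntr + 1, n), ratio = 0.85, seed = as.integer(seed))
}

## Training configuration used for the toy problem: small pooled-MLP with a
## step size suited to a few hundred samples.
toyTrainConfig <- function(epochs = 200) {
  list(epochs = epochs, poolSize = 16L, hidden = 64L, lr = 1e-2, seed = 1L)
}

dotValidationMpjpe <- function(model, ds) {
  preds <- lapply(validIndices(ds), function(i)
    predictJoints(model, datasetSamples(ds)[[i]]$image))
  gts <- lapply(validIndices(ds), function(i) datasetSamples(ds)[[i]]$label)
  mpjpe(preds, gts, c(1, 1))
}
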