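## Coronal projection and dataset assembly. Images follow the radiographic
## front-view convention: row 1 = most superior, column 1 = most
## patient-right; with x = patient-left positive, the patient's left collar
## therefore lands at the larger column index.

#' Orthographic coronal projection of a body mesh
#'
#' Projects the mesh along the anterior--posterior axis onto a regular pixel
#' grid. Pixel values encode the normalized anterior depth of the frontmost
#' surface, rescaled per image into (0, 1]; background is exactly 0. Joints
#' are projected by dropping the y coordinate.
#'
#' @param body a \code{BodyModel}.
#' @param spacingMm isotropic pixel spacing of the full-body render (mm).
#' @param marginMm grid margin around the mesh bounding box (mm).
#' @param seed provenance seed stored on the image.
#' @return list with \code{image} (a \code{CoronalImage} covering the whole
#'   body) and \code{joints2d} (named k x 2 matrix of (row, col) pixel
#'   coordinates for every skeleton joint).
#' @export
projectCoronal <- function(body, spacingMm = 2.5, marginMm = 10, seed = 0L) {
  if (!is(body, "BodyModel")) stopInvalid("body must be a BodyModel")
  if (nrow(body@faces) < 1) stopInvalid("mesh has no faces")
  V <- body@vertices
  xr <- range(V[, 1]); zr <- range(V[, 3])
  ncol <- ceiling((diff(xr) + 2 * marginMm) / spacingMm)
  nrow <- ceiling((diff(zr) + 2 * marginMm) / spacingMm)
  origin <- c(xr[1] - marginMm + spacingMm / 2,  # x of pixel [1,1] center
              zr[2] + marginMm - spacingMm / 2)  # z of pixel [1,1] center
  depth <- cpp_render_mesh(V[, 1], V[, 2], V[, 3], body@faces,
                           origin[1], origin[2], spacingMm, spacingMm,
                           nrow, ncol)
  inside <- !is.na(depth)
  px <- matrix(0, nrow, ncol)
  if (any(inside)) {
    d <- depth[inside]
    rng <- range(d)
    px[inside] <- if (rng[2] > rng[1])
      0.05 + 0.95 * (d - rng[1]) / (rng[2] - rng[1]) else 1
  }
  img <- new("CoronalImage", pixels = px,
             pixelSpacingMm = c(spacingMm, spacingMm),
             cropOriginMm = origin, sourceSeed = as.integer(seed))
  j2d <- patientToPixel(body@joints[, 1], body@joints[, 3],
                        origin, c(spacingMm, spacingMm))
  rownames(j2d) <- rownames(body@joints)
  list(image = img, joints2d = j2d)
}

## Bilinear sample of matrix P at fractional (row, col) target grids given
## as vectors fr (length H) and fc (length W); outside-source samples are 0.
bilinearResample <- function(P, fr, fc) {
  nr <- nrow(P); nc <- ncol(P)
  r0 <- floor(fr); c0 <- floor(fc)
  ar <- fr - r0; ac <- fc - c0
  gi <- function(r, c) {
    ok <- outer(r >= 1 & r <= nr, c >= 1 & c <= nc)
    rr <- pmin(pmax(r, 1), nr); cc <- pmin(pmax(c, 1), nc)
    out <- P[rr, cc, drop = FALSE]
    out[!ok] <- 0
    out
  }
  gi(r0, c0) * outer(1 - ar, 1 - ac) +
    gi(r0, c0 + 1) * outer(1 - ar, ac) +
    gi(r0 + 1, c0) * outer(ar, 1 - ac) +
    gi(r0 + 1, c0 + 1) * outer(ar, ac)
}

#' Randomized torso crop of a full-body coronal image
#'
#' Emulates the scan range of a breast-treatment CT: the upper crop boundary
#' is drawn uniformly between the Nose and Head joint rows, the lower
#' boundary uniformly between the Spine2 and Spine1 rows. The window is made
#' square in mm by centering laterally on the silhouette midline, then
#' resampled to \code{size} x \code{size} pixels with isotropic spacing.
#' The three regression-target joints must fall inside the crop; the draw is
#' retried a bounded number of times otherwise.
#'
#' @param image full-body \code{CoronalImage} from \code{projectCoronal}.
#' @param joints2d named joint (row, col) matrix from \code{projectCoronal};
#'   must contain Head, Nose, Spine1, Spine2 and the three targets.
#' @param size output image side in pixels (default 200).
#' @param seed integer seed for the crop draw.
#' @param maxRetries bounded resampling attempts.
#' @return list with \code{image} (cropped \code{CoronalImage}) and
#'   \code{label} (a \code{JointLabel2D}).
#' @export
cropTorso <- function(image, joints2d, size = 200L, seed = 0L, maxRetries = 10L) {
  need <- c("Head", "Nose", "Spine1", "Spine2", targetJointNames())
  if (!all(need %in% rownames(joints2d)))
    stopInvalid(paste("joints2d must contain:", paste(need, collapse = ", ")))
  P <- image@pixels
  sp <- image@pixelSpacingMm
  org <- image@cropOriginMm
  rowz <- function(r) org[2] - (r - 1) * sp[1]
  for (attempt in seq_len(maxRetries)) {
    draws <- withSeed(deriveSeed(seed, attempt, 5L), stats::runif(2))
    rHead <- joints2d["Head", 1]; rNose <- joints2d["Nose", 1]
    rS2 <- joints2d["Spine2", 1]; rS1 <- joints2d["Spine1", 1]
    rU <- min(rHead, rNose) + draws[1] * abs(rNose - rHead)
    rL <- min(rS2, rS1) + draws[2] * abs(rS1 - rS2)
    zTop <- rowz(rU); zBot <- rowz(rL)
    hMm <- zTop - zBot
    if (hMm <= 0) next
    ## lateral window: square (width = height) centered on the silhouette
    ## midline within the vertical band
    rows <- max(1, floor(rU)):min(nrow(P), ceiling(rL))
    band <- P[rows, , drop = FALSE]
    colMass <- colSums(band > 0)
    if (sum(colMass) == 0) next
    midCol <- sum(seq_along(colMass) * colMass) / sum(colMass)
    midX <- org[1] + (midCol - 1) * sp[2]
    xLeft <- midX - hMm / 2
    spacingNew <- hMm / size
    ## target pixel centers in patient mm
    zCtr <- zTop - (seq_len(size) - 0.5) * spacingNew
    xCtr <- xLeft + (seq_len(size) - 0.5) * spacingNew
    fr <- (org[2] - zCtr) / sp[1] + 1
    fc <- (xCtr - org[1]) / sp[2] + 1
    newOrigin <- c(xLeft + spacingNew / 2, zTop - spacingNew / 2)
    ## transform target joints into cropped pixel coordinates
    tj <- joints2d[targetJointNames(), , drop = FALSE]
    jx <- org[1] + (tj[, 2] - 1) * sp[2]
    jz <- org[2] - (tj[, 1] - 1) * sp[1]
    lab <- patientToPixel(jx, jz, newOrigin, c(spacingNew, spacingNew))
    rownames(lab) <- targetJointNames()
    if (any(lab[, 1] < 0.5 | lab[, 1] > size + 0.5 |
            lab[, 2] < 0.5 | lab[, 2] > size + 0.5)) next
    px <- bilinearResample(P, fr, fc)
    px[px < 0] <- 0; px[px > 1] <- 1
    img <- new("CoronalImage", pixels = px,
               pixelSpacingMm = c(spacingNew, spacingNew),
               cropOriginMm = newOrigin, sourceSeed = as.integer(seed))
    return(list(image = img,
                label = new("JointLabel2D", coords = lab,
                            imageSize = c(as.integer(size), as.integer(size)))))
  }
  stopInvalid("could not draw a crop containing all target joints")
}

#' Build the synthetic training dataset
#'
#' Samples \code{n} randomized bodies, rescales each to the working height,
#' renders the coronal projection, applies the randomized torso crop, and
#' splits the samples into train/validation by a seeded shuffle. The
#' method's reference configuration is n = 3000 images of 200 x 200 pixels
#' with an 85:15 split.
#'
#' @param n number of samples (>= 2).
#' @param ratio train fraction in (0, 1) (default 0.85).
#' @param seed global integer seed; per-sample seeds are derived from it.
#' @param size image side in pixels.
#' @param targetHeightMm working body height (default 1617).
#' @param bounds shape-scale range.
#' @param projectionSpacingMm full-body render spacing.
#' @return a \code{SyntheticDataset}.
#' @export
buildDataset <- function(n, ratio = 0.85, seed = 0L, size = 200L,
                         targetHeightMm = 1617, bounds = c(0.8, 1.2),
                         projectionSpacingMm = 2.5) {
  if (!is.numeric(n) || n < 2) stopInvalid("n must be >= 2")
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stopInvalid("ratio must be in (0, 1)")
  n <- as.integer(n)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    params <- randomShapeParams(deriveSeed(seed, i, 1L), bounds)
    body <- scaleToHeight(sampleBody(params), targetHeightMm)
    pc <- projectCoronal(body, spacingMm = projectionSpacingMm,
                         seed = deriveSeed(seed, i, 1L))
    samples[[i]] <- cropTorso(pc$image, pc$joints2d, size = size,
                              seed = deriveSeed(seed, i, 2L))
  }
  perm <- withSeed(deriveSeed(seed, 0L, 3L), sample.int(n))
  nTrain <- round(ratio * n)
  new("SyntheticDataset", samples = samples,
      trainIdx = sort(perm[seq_len(nTrain)]),
      validIdx = sort(perm[setdiff(seq_len(n), seq_len(nTrain))]),
      ratio = ratio, seed = as.integer(seed))
}
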