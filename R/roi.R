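## ROI construction: four steps. (1) S-I boundaries from the predicted
## collar/Spine2 joints or from the breast contour extent; (2) chest width at
## the midline row between those boundaries; (3) lateral span = lrFraction of
## the chest width anchored at the ipsilateral silhouette edge; (4) chamfer
## the ipsilateral-superior corner by the retraction distance to exclude the
## mobile arm/armpit region.

#' Construct a boundary-shift configuration
#'
#' @param upperShiftMm,lowerShiftMm S-I extensions from the joints (defaults
#'   10 and 30 mm, the tuned optima).
#' @param lrFraction lateral span as a fraction of chest width (default 3/4).
#' @param retractionMm ipsilateral-corner chamfer distance (default 80 mm).
#' @param breastEvalSupMm,breastEvalInfMm extensions from a breast-only
#'   contour (defaults 27 and 12 mm).
#' @param ptvSupMm,ptvInfMm extensions from a PTV contour (defaults -24 and
#'   17 mm).
#' @return a \code{ShiftConfig}.
#' @export
shiftConfig <- function(upperShiftMm = 10, lowerShiftMm = 30,
                        lrFraction = 0.75, retractionMm = 80,
                        breastEvalSupMm = 27, breastEvalInfMm = 12,
                        ptvSupMm = -24, ptvInfMm = 17) {
  obj <- try(new("ShiftConfig", upperShiftMm = upperShiftMm,
                 lowerShiftMm = lowerShiftMm, lrFraction = lrFraction,
                 retractionMm = retractionMm, breastEvalSupMm = breastEvalSupMm,
                 breastEvalInfMm = breastEvalInfMm, ptvSupMm = ptvSupMm,
                 ptvInfMm = ptvInfMm), silent = TRUE)
  if (inherits(obj, "try-error"))
    stopInvalid(paste("invalid shift config:", attr(obj, "condition")$message))
  obj
}

#' Construct a breast contour descriptor
#'
#' @param superiorZMm,inferiorZMm patient-frame z of the contour boundaries.
#' @param laterality "left" or "right".
#' @param category "breast_eval" or "PTV".
#' @return a \code{BreastContour}.
#' @export
breastContourSpec <- function(superiorZMm, inferiorZMm, laterality, category) {
  obj <- try(new("BreastContour", superiorZMm = superiorZMm,
                 inferiorZMm = inferiorZMm, laterality = laterality,
                 category = category), silent = TRUE)
  if (inherits(obj, "try-error"))
    stopInvalid(paste("invalid breast contour:", attr(obj, "condition")$message))
  obj
}

#' S-I ROI boundaries from predicted joints
#'
#' Upper boundary: mean of the two collar-joint z's plus the upper shift.
#' Lower boundary: Spine2 z minus the lower shift.
#'
#' @param joints named k x 3 matrix (mm) containing LeftCollar, RightCollar
#'   and Spine2.
#' @param cfg a \code{ShiftConfig}.
#' @return named numeric c(upperZ, lowerZ) in mm.
#' @export
siBoundsFromJoints <- function(joints, cfg = shiftConfig()) {
  need <- targetJointNames()
  if (!all(need %in% rownames(joints)))
    stopInvalid("joints must contain LeftCollar, RightCollar, Spine2")
  upper <- mean(joints[c("LeftCollar", "RightCollar"), 3]) + cfg@upperShiftMm
  lower <- joints["Spine2", 3] - cfg@lowerShiftMm
  if (!(upper > lower))
    stopDegenerate("upper boundary not above lower boundary")
  c(upperZ = unname(upper), lowerZ = unname(lower))
}

#' S-I ROI boundaries from a breast contour
#'
#' Applies the per-category extensions to the contour's S-I extent. A
#' negative superior extension (the PTV default) places the ROI's upper
#' boundary inferior of the contour's superior boundary.
#'
#' @param contour a \code{BreastContour}.
#' @param cfg a \code{ShiftConfig}.
#' @return named numeric c(upperZ, lowerZ) in mm.
#' @export
siBoundsFromBreast <- function(contour, cfg = shiftConfig()) {
  if (!is(contour, "BreastContour")) stopInvalid("contour must be a BreastContour")
  validObject(contour)
  ext <- if (contour@category == "breast_eval")
    c(cfg@breastEvalSupMm, cfg@breastEvalInfMm)
  else c(cfg@ptvSupMm, cfg@ptvInfMm)
  upper <- contour@superiorZMm + ext[1]
  lower <- contour@inferiorZMm - ext[2]
  if (!(upper > lower))
    stopDegenerate("upper boundary not above lower boundary")
  c(upperZ = unname(upper), lowerZ = unname(lower))
}

#' Chest width at the ROI midline
#'
#' Measures the lateral extent of the body silhouette at the row midway
#' between the upper and lower ROI boundaries, returning the outer edge
#' positions for lateral anchoring.
#'
#' @param silhouette a \code{BodySilhouette}.
#' @param upperZ,lowerZ S-I boundaries in mm.
#' @param laterality "left" or "right" treated side; decides which edge is
#'   ipsilateral (patient-left is the +x edge).
#' @return list: \code{widthMm}, \code{ipsiEdgeX}, \code{contraEdgeX},
#'   \code{midZ}.
#' @export
chestWidth <- function(silhouette, upperZ, lowerZ, laterality = "left") {
  if (!is(silhouette, "BodySilhouette")) stopInvalid("silhouette must be a BodySilhouette")
  if (!laterality %in% c("left", "right")) stopInvalid("laterality must be 'left' or 'right'")
  midZ <- (upperZ + lowerZ) / 2
  sp <- silhouette@spacingMm; org <- silhouette@originMm
  r <- round((org[2] - midZ) / sp[1] + 1)
  M <- silhouette@mask
  if (r < 1 || r > nrow(M)) stopDegenerate("midline row outside the silhouette grid")
  cols <- which(M[r, ])
  if (length(cols) == 0) stopDegenerate("midline row does not intersect the silhouette")
  xMin <- org[1] + (min(cols) - 1) * sp[2] - sp[2] / 2
  xMax <- org[1] + (max(cols) - 1) * sp[2] + sp[2] / 2
  if (laterality == "left") {
    list(widthMm = xMax - xMin, ipsiEdgeX = xMax, contraEdgeX = xMin, midZ = midZ)
  } else {
    list(widthMm = xMax - xMin, ipsiEdgeX = xMin, contraEdgeX = xMax, midZ = midZ)
  }
}

## Shared polygon constructor from the four boundary positions. Used by
## buildRoi and by the synthetic-cohort pseudo-clinical ROI so that equal
## boundary values yield bit-identical polygons.
roiFromBounds <- function(upperZ, lowerZ, ipsiX, contraX, laterality, cfg,
                          provenance) {
  upperZ <- unname(upperZ); lowerZ <- unname(lowerZ)
  ipsiX <- unname(ipsiX); contraX <- unname(contraX)
  s <- if (laterality == "left") 1 else -1
  span <- s * (ipsiX - contraX)
  if (span <= 0 || upperZ <= lowerZ)
    stopDegenerate("degenerate ROI bounds")
  ret <- cfg@retractionMm
  height <- upperZ - lowerZ
  chamfer <- NULL
  if (ret > 0 && ret < height && ret < span) {
    p1 <- c(ipsiX - s * ret, upperZ)   # on the superior edge
    p2 <- c(ipsiX, upperZ - ret)       # on the ipsilateral edge
    poly <- rbind(c(contraX, lowerZ), c(ipsiX, lowerZ), p2, p1,
                  c(contraX, upperZ))
    chamfer <- rbind(p1, p2)
  } else {
    if (ret > 0)
      warning("retraction exceeds an ROI edge; falling back to the plain rectangle")
    poly <- rbind(c(contraX, lowerZ), c(ipsiX, lowerZ),
                  c(ipsiX, upperZ), c(contraX, upperZ))
  }
  colnames(poly) <- c("x", "z")
  new("ROIRegion", polygon = poly, laterality = laterality,
      provenance = provenance,
      landmarks = list(upperZ = upperZ, lowerZ = lowerZ, ipsiX = ipsiX,
                       contraX = contraX, chamfer = chamfer))
}

#' Assemble the ROI polygon
#'
#' Builds the rectangle spanning the S-I boundaries, anchored at the
#' ipsilateral silhouette edge and extending \code{lrFraction} of the chest
#' width toward the contralateral side, then replaces the
#' ipsilateral-superior corner by a straight chamfer between the two points
#' \code{retractionMm} along the adjacent edges. If the retraction exceeds an
#' edge length the chamfer is skipped with a warning.
#'
#' @param upperZ,lowerZ S-I boundaries (mm).
#' @param chest output of \code{\link{chestWidth}}.
#' @param laterality "left" or "right".
#' @param cfg a \code{ShiftConfig}.
#' @param provenance "body" or "breast".
#' @return an \code{ROIRegion} (5 vertices chamfered, 4 on fallback).
#' @export
buildRoi <- function(upperZ, lowerZ, chest, laterality, cfg = shiftConfig(),
                     provenance = "body") {
  s <- if (laterality == "left") 1 else -1
  ipsiX <- chest$ipsiEdgeX
  contraX <- ipsiX - s * cfg@lrFraction * chest$widthMm
  roiFromBounds(upperZ, lowerZ, ipsiX, contraX, laterality, cfg, provenance)
}

#' Body-contour-based automated ROI
#'
#' Composition of the four construction steps from joint locations: either
#' ground-truth/predicted joints in mm, or a trained model plus a cropped
#' image from which joints are predicted and mapped back to mm.
#'
#' @param silhouette a \code{BodySilhouette}.
#' @param joints named k x 3 matrix (mm), or NULL to predict.
#' @param laterality "left" or "right".
#' @param cfg a \code{ShiftConfig}.
#' @param model,image \code{JointPredictor} and \code{CoronalImage}; used
#'   when \code{joints} is NULL.
#' @return an \code{ROIRegion} with provenance "body".
#' @export
generateAroiBody <- function(silhouette, joints = NULL, laterality = "left",
                             cfg = shiftConfig(), model = NULL, image = NULL) {
  if (is.null(joints)) {
    if (is.null(model) || is.null(image))
      stopInvalid("either joints or (model, image) must be supplied")
    lab <- predictJoints(model, image)
    mm <- pixelToPatient(lab@coords[, 1], lab@coords[, 2],
                         image@cropOriginMm, image@pixelSpacingMm)
    joints <- cbind(x = mm[, "x"], y = 0, z = mm[, "z"])
    rownames(joints) <- rownames(lab@coords)
  }
  b <- siBoundsFromJoints(joints, cfg)
  chest <- chestWidth(silhouette, b["upperZ"], b["lowerZ"], laterality)
  buildRoi(b["upperZ"], b["lowerZ"], chest, laterality, cfg, provenance = "body")
}

#' Breast-contour-based automated ROI
#'
#' Composition of the four construction steps from the delineated breast's
#' S-I extent; laterality is taken from the contour.
#'
#' @param silhouette a \code{BodySilhouette}.
#' @param contour a \code{BreastContour}.
#' @param cfg a \code{ShiftConfig}.
#' @return an \code{ROIRegion} with provenance "breast".
#' @export
generateAroiBreast <- function(silhouette, contour, cfg = shiftConfig()) {
  b <- siBoundsFromBreast(contour, cfg)
  chest <- chestWidth(silhouette, b["upperZ"], b["lowerZ"], contour@laterality)
  buildRoi(b["upperZ"], b["lowerZ"], chest, contour@laterality, cfg,
           provenance = "breast")
}

#' Define a raster grid
#'
#' A common pixel grid covering the bounding box of one or more ROI polygons
#' (and/or masks), used for Dice comparisons.
#'
#' @param ... \code{ROIRegion} and/or \code{CoronalMask} objects.
#' @param spacingMm isotropic pixel spacing (default 1 mm).
#' @param marginMm margin around the union bounding box.
#' @return list: \code{originMm}, \code{spacingMm}, \code{dim}.
#' @export
roiGrid <- function(..., spacingMm = 1, marginMm = 5) {
  objs <- list(...)
  xs <- c(); zs <- c()
  for (o in objs) {
    if (is(o, "ROIRegion")) {
      xs <- c(xs, range(o@polygon[, 1])); zs <- c(zs, range(o@polygon[, 2]))
    } else if (is(o, "CoronalMask")) {
      sp <- o@spacingMm; org <- o@originMm
      xs <- c(xs, org[1] - sp[2] / 2, org[1] + (ncol(o@mask) - 0.5) * sp[2])
      zs <- c(zs, org[2] - (nrow(o@mask) - 0.5) * sp[1], org[2] + sp[1] / 2)
    } else stopInvalid("roiGrid accepts ROIRegion or CoronalMask objects")
  }
  xr <- range(xs) + c(-marginMm, marginMm)
  zr <- range(zs) + c(-marginMm, marginMm)
  list(originMm = c(xr[1] + spacingMm / 2, zr[2] - spacingMm / 2),
       spacingMm = c(spacingMm, spacingMm),
       dim = c(ceiling(diff(zr) / spacingMm), ceiling(diff(xr) / spacingMm)))
}

#' Rasterize an ROI polygon
#'
#' A pixel belongs to the mask iff its center lies inside the polygon
#' (even-odd rule); the mask area times the pixel area converges to the
#' polygon's shoelace area as the spacing shrinks.
#'
#' @param roi an \code{ROIRegion}.
#' @param grid grid spec from \code{\link{roiGrid}} (or a \code{CoronalMask}
#'   whose grid is reused). Must cover the polygon.
#' @return a \code{CoronalMask}.
#' @export
rasterizeRoi <- function(roi, grid) {
  if (!is(roi, "ROIRegion")) stopInvalid("roi must be an ROIRegion")
  if (is(grid, "CoronalMask"))
    grid <- list(originMm = grid@originMm, spacingMm = grid@spacingMm,
                 dim = dim(grid@mask))
  sp <- grid$spacingMm; org <- grid$originMm; dm <- grid$dim
  xlim <- c(org[1] - sp[2] / 2, org[1] + (dm[2] - 0.5) * sp[2])
  zlim <- c(org[2] - (dm[1] - 0.5) * sp[1], org[2] + sp[1] / 2)
  poly <- roi@polygon
  if (min(poly[, 1]) < xlim[1] || max(poly[, 1]) > xlim[2] ||
      min(poly[, 2]) < zlim[1] || max(poly[, 2]) > zlim[2])
    stopInvalid("grid does not cover the polygon")
  mask <- cpp_polygon_mask(poly[, 1], poly[, 2], org[1], org[2],
                           sp[2], sp[1], dm[1], dm[2])
  new("CoronalMask", mask = mask, spacingMm = sp, originMm = org)
}

#' Coronal silhouette of a body
#'
#' Orthographic coronal projection of the body's surface, keeping the
#' largest connected component of the covered pixels.
#'
#' @param body a \code{BodyModel}.
#' @param spacingMm pixel spacing (default 2 mm).
#' @return a \code{BodySilhouette}.
#' @export
silhouetteFromBody <- function(body, spacingMm = 2) {
  pc <- projectCoronal(body, spacingMm = spacingMm)
  m <- pc$image@pixels > 0
  keep <- cpp_largest_component(m)
  new("BodySilhouette", mask = keep, spacingMm = pc$image@pixelSpacingMm,
      originMm = pc$image@cropOriginMm)
}
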