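#' @name accessors
#' @title Accessors for sgroi classes
#' @description Slot accessors for the package's S4 classes. Use these rather
#'   than \code{@} access.
#' @param object an sgroi S4 object.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(object) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("joints", function(object) standardGeneric("joints"))
#' @rdname accessors
#' @export
setGeneric("heightMm", function(object) standardGeneric("heightMm"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("cropOrigin", function(object) standardGeneric("cropOrigin"))
#' @rdname accessors
#' @export
setGeneric("labelCoords", function(object) standardGeneric("labelCoords"))
#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setGeneric("roiPolygon", function(object) standardGeneric("roiPolygon"))
#' @rdname accessors
#' @export
setGeneric("roiLandmarks", function(object) standardGeneric("roiLandmarks"))
#' @rdname accessors
#' @export
setGeneric("laterality", function(object) standardGeneric("laterality"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("category", function(object) standardGeneric("category"))
#' @rdname accessors
#' @export
setGeneric("superiorZ", function(object) standardGeneric("superiorZ"))
#' @rdname accessors
#' @export
setGeneric("inferiorZ", function(object) standardGeneric("inferiorZ"))
#' @rdname accessors
#' @export
setGeneric("trainIndices", function(object) standardGeneric("trainIndices"))
#' @rdname accessors
#' @export
setGeneric("validIndices", function(object) standardGeneric("validIndices"))
#' @rdname accessors
#' @export
setGeneric("datasetSamples", function(object) standardGeneric("datasetSamples"))
#' @rdname accessors
#' @export
setGeneric("clinicalRoi", function(object) standardGeneric("clinicalRoi"))
#' @rdname accessors
#' @export
setGeneric("breastContour", function(object) standardGeneric("breastContour"))
#' @rdname accessors
#' @export
setGeneric("bodySilhouette", function(object) standardGeneric("bodySilhouette"))

#' @rdname accessors
setMethod("vertices", "BodyModel", function(object) object@vertices)
#' @rdname accessors
setMethod("faces", "BodyModel", function(object) object@faces)
#' @rdname accessors
setMethod("joints", "BodyModel", function(object) object@joints)
#' @rdname accessors
setMethod("heightMm", "BodyModel", function(object) object@heightMm)
#' @rdname accessors
setMethod("joints", "SyntheticPatient", function(object) object@joints)
#' @rdname accessors
setMethod("pixels", "CoronalImage", function(object) object@pixels)
#' @rdname accessors
setMethod("pixelSpacing", "CoronalImage", function(object) object@pixelSpacingMm)
#' @rdname accessors
setMethod("cropOrigin", "CoronalImage", function(object) object@cropOriginMm)
#' @rdname accessors
setMethod("labelCoords", "JointLabel2D", function(object) object@coords)
#' @rdname accessors
setMethod("maskMatrix", "CoronalMask", function(object) object@mask)
#' @rdname accessors
setMethod("pixelSpacing", "CoronalMask", function(object) object@spacingMm)
#' @rdname accessors
setMethod("cropOrigin", "CoronalMask", function(object) object@originMm)
#' @rdname accessors
setMethod("roiPolygon", "ROIRegion", function(object) object@polygon)
#' @rdname accessors
setMethod("roiLandmarks", "ROIRegion", function(object) object@landmarks)
#' @rdname accessors
setMethod("laterality", "ROIRegion", function(object) object@laterality)
#' @rdname accessors
setMethod("provenance", "ROIRegion", function(object) object@provenance)
#' @rdname accessors
setMethod("laterality", "BreastContour", function(object) object@laterality)
#' @rdname accessors
setMethod("category", "BreastContour", function(object) object@category)
#' @rdname accessors
setMethod("superiorZ", "BreastContour", function(object) object@superiorZMm)
#' @rdname accessors
setMethod("inferiorZ", "BreastContour", function(object) object@inferiorZMm)
#' @rdname accessors
setMethod("trainIndices", "SyntheticDataset", function(object) object@trainIdx)
#' @rdname accessors
setMethod("validIndices", "SyntheticDataset", function(object) object@validIdx)
#' @rdname accessors
setMethod("datasetSamples", "SyntheticDataset", function(object) object@samples)
#' @rdname accessors
setMethod("clinicalRoi", "SyntheticPatient", function(object) object@clinicalRoi)
#' @rdname accessors
setMethod("breastContour", "SyntheticPatient", function(object) object@contour)
#' @rdname accessors
setMethod("bodySilhouette", "SyntheticPatient", function(object) object@silhouette)

setMethod("show", "BodyModel", function(object) {
  cat(sprintf("BodyModel: %d vertices, %d faces, %d joints, height %.1f mm (seed %d)\n",
              nrow(object@vertices), nrow(object@faces), nrow(object@joints),
              object@heightMm, object@shapeSeed))
})

setMethod("show", "CoronalImage", function(object) {
  cat(sprintf("CoronalImage: %d x %d px, spacing (%.3f, %.3f) mm/px, origin (%.1f, %.1f) mm\n",
              nrow(object@pixels), ncol(object@pixels),
              object@pixelSpacingMm[1], object@pixelSpacingMm[2],
              object@cropOriginMm[1], object@cropOriginMm[2]))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d samples (%d train / %d validation, ratio %.2f, seed %d)\n",
              length(object@samples), length(object@trainIdx),
              length(object@validIdx), object@ratio, object@seed))
})

setMethod("show", "CoronalMask", function(object) {
  cat(sprintf("%s: %d x %d px, %d on, spacing (%.2f, %.2f) mm/px\n",
              class(object), nrow(object@mask), ncol(object@mask),
              sum(object@mask), object@spacingMm[1], object@spacingMm[2]))
})

setMethod("show", "BreastContour", function(object) {
  cat(sprintf("BreastContour (%s, %s): S-I extent [%.1f, %.1f] mm\n",
              object@laterality, object@category,
              object@inferiorZMm, object@superiorZMm))
})

setMethod("show", "ROIRegion", function(object) {
  cat(sprintf("ROIRegion (%s, %s-based): %d vertices, area %.0f mm^2, z [%.1f, %.1f]\n",
              object@laterality, object@provenance, nrow(object@polygon),
              polygonArea(object@polygon), object@landmarks$lowerZ,
              object@landmarks$upperZ))
})

setMethod("show", "JointPredictor", function(object) {
  cat(sprintf("JointPredictor (%s): input %d x %d, trained %d epochs, final val loss %.3g\n",
              object@backbone, object@inputSize[1], object@inputSize[2],
              object@trainMeta$epochs,
              utils::tail(object@trainMeta$validLoss, 1)))
})

setMethod("show", "SyntheticPatient", function(object) {
  cat(sprintf("SyntheticPatient (%s, %s): noise sd %.1f mm, seed %d\n",
              object@contour@laterality, object@contour@category,
              object@noiseSdMm, object@seed))
})
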