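#' Parametric body-shape parameters
#'
#' Multiplicative scale factors applied to the procedural body template, plus
#' the RNG seed that makes a sampled body reproducible. All scales must lie
#' within \code{bounds} (default 0.8--1.2), chosen to span the anthropometric
#' spread of a whole-breast radiotherapy cohort without producing degenerate
#' bodies.
#'
#' @slot torsoWidthScale,torsoDepthScale,shoulderWidthScale,limbLengthScale
#'   positive multiplicative scales on the template dimensions.
#' @slot rngSeed integer seed.
#' @slot bounds length-2 numeric, allowed scale range.
#' @exportClass ShapeParams
setClass("ShapeParams",
  representation(torsoWidthScale = "numeric", torsoDepthScale = "numeric",
                 shoulderWidthScale = "numeric", limbLengthScale = "numeric",
                 rngSeed = "integer", bounds = "numeric"),
  prototype(torsoWidthScale = 1, torsoDepthScale = 1, shoulderWidthScale = 1,
            limbLengthScale = 1, rngSeed = 0L, bounds = c(0.8, 1.2)))

setValidity("ShapeParams", function(object) {
  sc <- c(object@torsoWidthScale, object@torsoDepthScale,
          object@shoulderWidthScale, object@limbLengthScale)
  if (length(object@bounds) != 2 || object@bounds[1] <= 0 ||
      object@bounds[1] >= object@bounds[2])
    return("bounds must be an increasing positive pair")
  if (any(!is.finite(sc)) || any(sc < object@bounds[1]) || any(sc > object@bounds[2]))
    return(sprintf("all scales must lie in [%g, %g]",
                   object@bounds[1], object@bounds[2]))
  TRUE
})

#' Posed synthetic human body
#'
#' Triangle surface mesh of an arms-raised human together with a named joint
#' skeleton, in the patient frame (x patient-left, y anterior, z superior; mm).
#'
#' @slot vertices numeric n x 3 matrix (x, y, z in mm).
#' @slot faces integer m x 3 matrix of 1-based vertex indices.
#' @slot joints named numeric k x 3 matrix; rownames are joint names.
#' @slot shapeSeed integer seed the body was sampled with.
#' @slot heightMm superior--inferior vertex extent in mm.
#' @exportClass BodyModel
setClass("BodyModel",
  representation(vertices = "matrix", faces = "matrix", joints = "matrix",
                 shapeSeed = "integer", heightMm = "numeric"))

setValidity("BodyModel", function(object) {
  req <- c("Head", "Nose", "LeftCollar", "RightCollar", "Spine1", "Spine2",
           "LeftShoulder", "RightShoulder")
  if (ncol(object@vertices) != 3) return("vertices must be n x 3")
  if (ncol(object@faces) != 3) return("faces must be m x 3")
  miss <- setdiff(req, rownames(object@joints))
  if (length(miss)) return(paste("missing joints:", paste(miss, collapse = ", ")))
  lo <- apply(object@vertices, 2, min); hi <- apply(object@vertices, 2, max)
  j <- object@joints
  if (any(j < matrix(lo, nrow(j), 3, byrow = TRUE) - 1e-6) ||
      any(j > matrix(hi, nrow(j), 3, byrow = TRUE) + 1e-6))
    return("every joint must lie inside the mesh bounding box")
  ext <- hi[3] - lo[3]
  if (abs(ext - object@heightMm) > 1)
    return("heightMm must equal the S-I vertex extent within 1 mm")
  if (abs(j["LeftCollar", 3] - j["RightCollar", 3]) > 15)
    return("collar joints must have S-I coordinates within 15 mm")
  TRUE
})

#' Cropped coronal projection image
#'
#' Square grayscale depth-shaded silhouette of the torso window, with the
#' pixel grid geometry needed to map pixels back to patient mm coordinates.
#' Background pixels are exactly 0; body pixels are in (0, 1].
#'
#' @slot pixels H x W numeric matrix in [0, 1].
#' @slot pixelSpacingMm (row, col) spacing in mm/pixel.
#' @slot cropOriginMm patient (x, z) of the center of pixel [1, 1].
#' @slot sourceSeed integer provenance seed.
#' @exportClass CoronalImage
setClass("CoronalImage",
  representation(pixels = "matrix", pixelSpacingMm = "numeric",
                 cropOriginMm = "numeric", sourceSeed = "integer"))

setValidity("CoronalImage", function(object) {
  p <- object@pixels
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    return("pixels must be finite in [0, 1]")
  if (length(object@pixelSpacingMm) != 2 || any(object@pixelSpacingMm <= 0))
    return("pixelSpacingMm must be two positive reals")
  if (length(object@cropOriginMm) != 2)
    return("cropOriginMm must be (x, z)")
  TRUE
})

#' 2D joint labels for a coronal image
#'
#' Real-valued (row, col) pixel coordinates of the three regression targets:
#' LeftCollar, RightCollar and Spine2.
#'
#' @slot coords 3 x 2 numeric matrix, rownames the joint names,
#'   columns (row, col).
#' @slot imageSize (H, W) of the image the labels refer to.
#' @exportClass JointLabel2D
setClass("JointLabel2D",
  representation(coords = "matrix", imageSize = "integer"))

setValidity("JointLabel2D", function(object) {
  if (!identical(sort(rownames(object@coords)), sort(targetJointNames())))
    return("coords must be labeled LeftCollar, RightCollar, Spine2")
  H <- object@imageSize[1]; W <- object@imageSize[2]
  if (any(object@coords[, 1] < 0.5) || any(object@coords[, 1] > H + 0.5) ||
      any(object@coords[, 2] < 0.5) || any(object@coords[, 2] > W + 0.5))
    return("all label coordinates must fall inside the image")
  TRUE
})

#' Synthetic training dataset
#'
#' Paired coronal images and joint labels plus a deterministic
#' train/validation split.
#'
#' @slot samples list; each element is \code{list(image = CoronalImage,
#'   label = JointLabel2D)}.
#' @slot trainIdx,validIdx integer index vectors partitioning the samples.
#' @slot ratio train fraction.
#' @slot seed integer seed the dataset was built with.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(samples = "list", trainIdx = "integer", validIdx = "integer",
                 ratio = "numeric", seed = "integer"))

setValidity("SyntheticDataset", function(object) {
  n <- length(object@samples)
  if (length(intersect(object@trainIdx, object@validIdx)))
    return("train and validation indices must be disjoint")
  if (!setequal(c(object@trainIdx, object@validIdx), seq_len(n)))
    return("split must cover all samples")
  if (length(object@trainIdx) != round(object@ratio * n))
    return("train size must equal round(ratio * n)")
  TRUE
})

#' Binary coronal mask on a pixel grid
#'
#' Shared raster container for body silhouettes and rasterized ROIs.
#'
#' @slot mask logical H x W matrix.
#' @slot spacingMm (row, col) spacing in mm/pixel.
#' @slot originMm patient (x, z) of the center of pixel [1, 1].
#' @exportClass CoronalMask
setClass("CoronalMask",
  representation(mask = "matrix", spacingMm = "numeric", originMm = "numeric"))

setValidity("CoronalMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@spacingMm) != 2 || any(object@spacingMm <= 0))
    return("spacingMm must be two positive reals")
  TRUE
})

#' Coronal body silhouette
#'
#' The external body contour projected to the coronal plane: a non-empty,
#' single-connected-component binary mask.
#'
#' @exportClass BodySilhouette
setClass("BodySilhouette", contains = "CoronalMask")

setValidity("BodySilhouette", function(object) {
  if (!any(object@mask)) return("silhouette must be non-empty")
  keep <- cpp_largest_component(object@mask)
  if (sum(keep) != sum(object@mask))
    return("silhouette must be a single connected component")
  TRUE
})

#' Superior--inferior extent of the delineated breast
#'
#' @slot superiorZMm,inferiorZMm patient z of the breast contour boundaries.
#' @slot laterality "left" or "right" (treated side).
#' @slot category "breast_eval" (breast only) or "PTV" (breast plus local
#'   lymph nodes); each category has its own boundary extension constants.
#' @exportClass BreastContour
setClass("BreastContour",
  representation(superiorZMm = "numeric", inferiorZMm = "numeric",
                 laterality = "character", category = "character"))

setValidity("BreastContour", function(object) {
  if (!object@laterality %in% c("left", "right"))
    return("laterality must be 'left' or 'right'")
  if (!object@category %in% c("breast_eval", "PTV"))
    return("category must be 'breast_eval' or 'PTV'")
  if (!(object@superiorZMm > object@inferiorZMm))
    return("superiorZMm must exceed inferiorZMm")
  TRUE
})

#' Tunable boundary extensions of the ROI construction
#'
#' Defaults are the construction constants of the method: a 10 mm superior and
#' 30 mm inferior shift from the predicted joints, a lateral span of 3/4 of
#' the chest width, an 80 mm ipsilateral-corner retraction, and per-category
#' breast-contour extensions of (27, 12) mm for breast-only contours and
#' (-24, 17) mm for PTV contours.
#'
#' @slot upperShiftMm,lowerShiftMm superior/inferior extension from joints.
#' @slot lrFraction fraction of chest width spanned laterally, in (0, 1].
#' @slot retractionMm chamfer retraction along each edge at the
#'   ipsilateral-superior corner.
#' @slot breastEvalSupMm,breastEvalInfMm extensions from a breast_eval contour.
#' @slot ptvSupMm,ptvInfMm extensions from a PTV contour (superior value is
#'   negative: that ROI boundary sits inferior of the contour boundary).
#' @exportClass ShiftConfig
setClass("ShiftConfig",
  representation(upperShiftMm = "numeric", lowerShiftMm = "numeric",
                 lrFraction = "numeric", retractionMm = "numeric",
                 breastEvalSupMm = "numeric", breastEvalInfMm = "numeric",
                 ptvSupMm = "numeric", ptvInfMm = "numeric"),
  prototype(upperShiftMm = 10, lowerShiftMm = 30, lrFraction = 0.75,
            retractionMm = 80, breastEvalSupMm = 27, breastEvalInfMm = 12,
            ptvSupMm = -24, ptvInfMm = 17))

setValidity("ShiftConfig", function(object) {
  v <- c(object@upperShiftMm, object@lowerShiftMm, object@breastEvalSupMm,
         object@breastEvalInfMm, object@ptvSupMm, object@ptvInfMm)
  if (any(!is.finite(v))) return("shifts must be finite")
  if (object@lrFraction <= 0 || object@lrFraction > 1)
    return("lrFraction must be in (0, 1]")
  if (object@retractionMm < 0) return("retractionMm must be >= 0")
  TRUE
})

#' ROI polygon in the patient coronal plane
#'
#' The constructed region of interest as a simple polygon, with the four
#' construction landmarks retained so the polygon can be re-derived.
#'
#' @slot polygon ordered n x 2 matrix of (x, z) vertices in mm.
#' @slot laterality "left" or "right".
#' @slot provenance "body" (joint-driven) or "breast" (contour-driven).
#' @slot landmarks list: upperZ, lowerZ, ipsiX, contraX, chamfer (2 x 2 matrix
#'   of the retraction points, or NULL when the chamfer fell back).
#' @exportClass ROIRegion
setClass("ROIRegion",
  representation(polygon = "matrix", laterality = "character",
                 provenance = "character", landmarks = "list"))

setValidity("ROIRegion", function(object) {
  if (ncol(object@polygon) != 2 || nrow(object@polygon) < 3)
    return("polygon must be an n x 2 matrix with n >= 3")
  if (!object@laterality %in% c("left", "right"))
    return("laterality must be 'left' or 'right'")
  if (!object@provenance %in% c("body", "breast"))
    return("provenance must be 'body' or 'breast'")
  if (polygonArea(object@polygon) <= 0) return("polygon must have positive area")
  TRUE
})

#' Trained joint-location regressor
#'
#' Backbone-agnostic container for a model mapping a cropped coronal image to
#' the six outputs (row, col) x (LeftCollar, RightCollar, Spine2). The default
#' backbone is a small pooled-feature multilayer perceptron trained with Adam
#' on a mean-squared-error loss over normalized coordinates.
#'
#' @slot backbone backbone identifier ("pool_mlp" or "linear").
#' @slot params list of learned weight matrices and normalization statistics.
#' @slot inputSize (H, W) the model accepts.
#' @slot trainMeta list: epochs run, final losses, seed, hyperparameters.
#' @exportClass JointPredictor
setClass("JointPredictor",
  representation(backbone = "character", params = "list",
                 inputSize = "integer", trainMeta = "list"))

#' Synthetic patient for end-to-end evaluation
#'
#' One simulated case: body, silhouette, ground-truth joints, breast contour,
#' and a pseudo-clinical ROI built from the true landmarks plus boundary
#' jitter. Stands in for a clinical cohort when none is available.
#'
#' @slot body a \code{BodyModel}.
#' @slot silhouette a \code{BodySilhouette}.
#' @slot joints named k x 3 matrix of ground-truth joints (mm).
#' @slot contour a \code{BreastContour}.
#' @slot clinicalRoi pseudo-clinical \code{ROIRegion}.
#' @slot noiseSdMm boundary jitter standard deviation used (mm).
#' @slot seed integer seed for this patient.
#' @exportClass SyntheticPatient
setClass("SyntheticPatient",
  representation(body = "BodyModel", silhouette = "BodySilhouette",
                 joints = "matrix", contour = "BreastContour",
                 clinicalRoi = "ROIRegion", noiseSdMm = "numeric",
                 seed = "integer"))
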