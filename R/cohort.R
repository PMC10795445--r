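## Synthetic patient cohort: silhouettes, ground-truth joints, breast
## contours and pseudo-clinical ROIs with controllable boundary jitter.
## Stands in for a clinical cohort when none is available: the
## pseudo-clinical ROI is the construction at the true shifts plus
## independent Gaussian jitter on each of its four boundary positions
## (mimicking inter-planner variability), and the breast contour is placed
## consistently with the per-category extension constants so the same
## reference supports both shift tuning and boundary-distance analysis.

#' Generate a synthetic patient cohort
#'
#' @param n number of patients (>= 1). The reference cohort sizes are 24
#'   (parameter tuning) and 39 (full cohort, 30 breast_eval : 9 PTV).
#' @param noiseSdMm standard deviation of the Gaussian jitter applied
#'   independently to each of the four pseudo-clinical ROI boundaries (mm).
#' @param seed global integer seed.
#' @param categoryMix length-2 numeric (breast_eval, PTV) mixing weights;
#'   counts are assigned as round(n * weight / sum).
#' @param lateralitySide "random", "left" or "right".
#' @param heightRangeMm sampled body heights (default 1493--1606 mm, the
#'   cohort's stature range).
#' @param cfg the true \code{ShiftConfig} the pseudo-clinical ROIs encode.
#' @param silhouetteSpacingMm silhouette raster spacing.
#' @return list of \code{SyntheticPatient} objects.
#' @export
makeCohort <- function(n, noiseSdMm = 0, seed = 0L,
                       categoryMix = c(breast_eval = 30, PTV = 9),
                       lateralitySide = "random",
                       heightRangeMm = c(1493, 1606),
                       cfg = shiftConfig(), silhouetteSpacingMm = 2) {
  if (!is.numeric(n) || n < 1) stopInvalid("n must be >= 1")
  if (!is.numeric(noiseSdMm) || noiseSdMm < 0) stopInvalid("noiseSdMm must be >= 0")
  if (length(categoryMix) != 2 || any(categoryMix < 0) || sum(categoryMix) <= 0)
    stopInvalid("categoryMix must be two non-negative weights with positive sum")
  if (!lateralitySide %in% c("random", "left", "right"))
    stopInvalid("lateralitySide must be 'random', 'left' or 'right'")
  n <- as.integer(n)
  nBreast <- round(n * categoryMix[1] / sum(categoryMix))
  categories <- c(rep("breast_eval", nBreast), rep("PTV", n - nBreast))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    si <- deriveSeed(seed, i, 11L)
    draws <- withSeed(si, list(scales = stats::runif(4, 0.8, 1.2),
                               height = stats::runif(1, heightRangeMm[1],
                                                     heightRangeMm[2]),
                               side = sample(c("left", "right"), 1),
                               jitter = stats::rnorm(4, 0, 1)))
    lat <- if (lateralitySide == "random") draws$side else lateralitySide
    params <- shapeParams(draws$scales[1], draws$scales[2], draws$scales[3],
                          draws$scales[4], rngSeed = si)
    body <- scaleToHeight(sampleBody(params), draws$height)
    sil <- silhouetteFromBody(body, spacingMm = silhouetteSpacingMm)
    jts <- body@joints
    ## true construction, then jitter the four boundary positions
    b <- siBoundsFromJoints(jts, cfg)
    chest <- chestWidth(sil, b["upperZ"], b["lowerZ"], lat)
    s <- if (lat == "left") 1 else -1
    ipsiX <- chest$ipsiEdgeX
    contraX <- ipsiX - s * cfg@lrFraction * chest$widthMm
    jit <- draws$jitter * noiseSdMm
    croi <- roiFromBounds(b["upperZ"] + jit[1], b["lowerZ"] + jit[2],
                          ipsiX + jit[3], contraX + jit[4],
                          lat, cfg, provenance = "body")
    ## breast contour placed so the true (noise-free) ROI sits exactly the
    ## per-category extensions away from its boundaries
    ext <- if (categories[i] == "breast_eval")
      c(cfg@breastEvalSupMm, cfg@breastEvalInfMm) else c(cfg@ptvSupMm, cfg@ptvInfMm)
    contour <- breastContourSpec(superiorZMm = unname(b["upperZ"] - ext[1]),
                                 inferiorZMm = unname(b["lowerZ"] + ext[2]),
                                 laterality = lat, category = categories[i])
    out[[i]] <- new("SyntheticPatient", body = body, silhouette = sil,
                    joints = jts, contour = contour, clinicalRoi = croi,
                    noiseSdMm = noiseSdMm, seed = si)
  }
  out
}
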