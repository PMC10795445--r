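## ROI comparison and boundary-shift tuning. All Dice computations are done
## on a common 1 mm/pixel raster over the union bounding box: sub-millimeter
## differences are below clinical relevance and the shared grid keeps the
## comparison exact.

#' Dice similarity coefficient between two masks
#'
#' DSC = 2 |A n B| / (|A| + |B|) on identical pixel grids. Two empty masks
#' are defined as DSC 1 with a warning.
#'
#' @param a,b \code{CoronalMask} objects on the same grid.
#' @return an object of class \code{DSCResult}: \code{dsc},
#'   \code{intersection}, \code{areaA}, \code{areaB}, \code{grid}.
#' @export
dsc <- function(a, b) {
  if (!is(a, "CoronalMask") || !is(b, "CoronalMask"))
    stopInvalid("a and b must be CoronalMask objects")
  if (!identical(dim(a@mask), dim(b@mask)) ||
      !isTRUE(all.equal(a@spacingMm, b@spacingMm)) ||
      !isTRUE(all.equal(a@originMm, b@originMm)))
    stopInvalid("masks must share an identical grid")
  areaA <- sum(a@mask); areaB <- sum(b@mask)
  inter <- sum(a@mask & b@mask)
  val <- if (areaA + areaB == 0) {
    warning("both masks are empty; DSC defined as 1")
    1
  } else 2 * inter / (areaA + areaB)
  structure(list(dsc = val, intersection = inter, areaA = areaA, areaB = areaB,
                 grid = list(dim = dim(a@mask), spacingMm = a@spacingMm,
                             originMm = a@originMm)),
            class = "DSCResult")
}

#' @export
print.DSCResult <- function(x, ...) {
  cat(sprintf("DSC = %.4f (|A|=%d, |B|=%d, |AnB|=%d on %dx%d px)\n",
              x$dsc, x$areaA, x$areaB, x$intersection,
              x$grid$dim[1], x$grid$dim[2]))
  invisible(x)
}

## Normalize a tuning/evaluation case into list(silhouette, joints,
## laterality, clinicalRoi, contour).
asCase <- function(x) {
  if (is(x, "SyntheticPatient"))
    return(list(silhouette = x@silhouette, joints = x@joints,
                laterality = x@contour@laterality, clinicalRoi = x@clinicalRoi,
                contour = x@contour))
  x
}

#' Grid-search tuning of the S-I boundary shifts
#'
#' For every (upper, lower) candidate pair, constructs the
#' body-contour-based ROI for each case, rasterizes it on the case's common
#' grid, and averages the Dice coefficient against the reference (clinical)
#' ROI. Returns the candidate pair maximizing the mean DSC; ties break
#' toward the smallest (upper, lower) lexicographically. The method's
#' candidate range is 0 to 45 mm in 5 mm steps.
#'
#' @param cases list of \code{SyntheticPatient} or lists with
#'   \code{silhouette}, \code{joints}, \code{laterality}, \code{clinicalRoi}.
#' @param candidates numeric vector of shift candidates (mm), used for both
#'   boundaries.
#' @param cfg base \code{ShiftConfig} supplying the non-tuned parameters.
#' @param gridSpacingMm raster spacing for the DSC grids.
#' @return an object of class \code{TuningResult}: \code{dscGrid} (upper x
#'   lower matrix of mean DSC), \code{best} (named upper/lower optimum),
#'   \code{candidates}, \code{nCases}.
#' @export
tuneShifts <- function(cases, candidates = seq(0, 45, by = 5),
                       cfg = shiftConfig(), gridSpacingMm = 1) {
  if (length(cases) < 1) stopInvalid("at least one reference case is required")
  if (length(candidates) < 1) stopInvalid("candidate set must be non-empty")
  cases <- lapply(cases, asCase)
  nu <- length(candidates)
  acc <- matrix(0, nu, nu,
                dimnames = list(upper = candidates, lower = candidates))
  used <- 0L
  maxCfg <- cfg
  maxCfg@upperShiftMm <- max(candidates)
  maxCfg@lowerShiftMm <- max(candidates)
  for (cs in cases) {
    ok <- TRUE
    contrib <- matrix(NA_real_, nu, nu)
    res <- try({
      widest <- generateAroiBody(cs$silhouette, cs$joints, cs$laterality, maxCfg)
      grid <- roiGrid(cs$clinicalRoi, widest, spacingMm = gridSpacingMm)
      refMask <- rasterizeRoi(cs$clinicalRoi, grid)
      for (iu in seq_len(nu)) for (il in seq_len(nu)) {
        cfgUL <- cfg
        cfgUL@upperShiftMm <- candidates[iu]
        cfgUL@lowerShiftMm <- candidates[il]
        roi <- generateAroiBody(cs$silhouette, cs$joints, cs$laterality, cfgUL)
        contrib[iu, il] <- dsc(rasterizeRoi(roi, grid), refMask)$dsc
      }
    }, silent = TRUE)
    if (inherits(res, "try-error") || anyNA(contrib)) {
      warning("a tuning case failed ROI construction and was skipped")
      ok <- FALSE
    }
    if (ok) { acc <- acc + contrib; used <- used + 1L }
  }
  if (used == 0L) stopInvalid("all tuning cases failed ROI construction")
  meanDsc <- acc / used
  ## argmax with lexicographic tie-break toward the smallest (upper, lower)
  best <- which(meanDsc == max(meanDsc), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  structure(list(dscGrid = meanDsc,
                 best = c(upperShiftMm = candidates[best[1]],
                          lowerShiftMm = candidates[best[2]]),
                 candidates = candidates, nCases = used),
            class = "TuningResult")
}

#' @export
print.TuningResult <- function(x, ...) {
  cat(sprintf("Shift tuning over %d cases: best upper %g mm / lower %g mm (mean DSC %.4f)\n",
              x$nCases, x$best["upperShiftMm"], x$best["lowerShiftMm"],
              max(x$dscGrid)))
  invisible(x)
}

#' Mean S-I distance between reference ROI and breast boundaries
#'
#' Signed distances between the reference ROI's S-I boundaries and the
#' breast contour's boundaries, averaged within each contour category.
#' Positive means the ROI boundary lies beyond the contour boundary, away
#' from the breast (superior of it at the top, inferior of it at the
#' bottom); the PTV category typically shows a negative superior distance.
#'
#' @param rois list of reference \code{ROIRegion} objects.
#' @param contours list of matching \code{BreastContour} objects.
#' @return named list per category present, each
#'   \code{c(superiorMm, inferiorMm, n)}; empty categories are omitted with
#'   a warning.
#' @export
meanBoundaryDistance <- function(rois, contours) {
  if (length(rois) != length(contours))
    stopInvalid("rois and contours must have equal length")
  if (length(rois) == 0) stopInvalid("at least one pair is required")
  cat_ <- vapply(contours, function(ct) ct@category, "")
  sup <- mapply(function(r, ct) r@landmarks$upperZ - ct@superiorZMm,
                rois, contours)
  inf <- mapply(function(r, ct) ct@inferiorZMm - r@landmarks$lowerZ,
                rois, contours)
  out <- list()
  for (cc in c("breast_eval", "PTV")) {
    sel <- cat_ == cc
    if (!any(sel)) {
      warning(sprintf("no cases in category '%s'; omitted", cc))
      next
    }
    out[[cc]] <- c(superiorMm = mean(sup[sel]), inferiorMm = mean(inf[sel]),
                   n = sum(sel))
  }
  out
}
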