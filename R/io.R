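## Plain-text interchange: OBJ meshes, JSON skeletons / ROIs / breast
## contours, PNG + JSON datasets, JSON model checkpoints.

#' Export a body mesh as Wavefront OBJ
#'
#' @param body a \code{BodyModel}.
#' @param path output .obj path.
#' @return \code{path}, invisibly.
#' @export
writeObj <- function(body, path) {
  V <- body@vertices; Fc <- body@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("f %d %d %d", Fc[, 1], Fc[, 2], Fc[, 3]), con)
  invisible(path)
}

#' Export a skeleton as JSON
#'
#' Writes \code{{joint_name: [x, y, z]}} in mm.
#'
#' @param joints named k x 3 joint matrix (or a \code{BodyModel}).
#' @param path output .json path.
#' @return \code{path}, invisibly.
#' @export
writeSkeletonJson <- function(joints, path) {
  if (is(joints, "BodyModel")) joints <- joints@joints
  obj <- lapply(seq_len(nrow(joints)), function(i) unname(joints[i, ]))
  names(obj) <- rownames(joints)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Write an ROI polygon as JSON
#'
#' @param roi an \code{ROIRegion}.
#' @param path output .json path.
#' @return \code{path}, invisibly.
#' @export
writeRoiJson <- function(roi, path) {
  lm <- roi@landmarks
  obj <- list(polygon_mm = unname(apply(roi@polygon, 1, as.numeric,
                                        simplify = FALSE)),
              laterality = roi@laterality, provenance = roi@provenance,
              landmarks = list(upper_z_mm = lm$upperZ, lower_z_mm = lm$lowerZ,
                               ipsi_x_mm = lm$ipsiX, contra_x_mm = lm$contraX,
                               chamfer_mm = if (is.null(lm$chamfer)) NULL else
                                 unname(apply(lm$chamfer, 1, as.numeric,
                                              simplify = FALSE))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read an ROI polygon from JSON
#'
#' @param path .json path written by \code{\link{writeRoiJson}}.
#' @return an \code{ROIRegion}.
#' @export
readRoiJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asXZ <- function(v) {
    m <- if (is.matrix(v)) v else matrix(unlist(v), ncol = 2, byrow = TRUE)
    dimnames(m) <- list(NULL, c("x", "z"))
    m
  }
  poly <- asXZ(obj$polygon_mm)
  ch <- obj$landmarks$chamfer_mm
  chamfer <- if (is.null(ch)) NULL else asXZ(ch)
  new("ROIRegion", polygon = poly, laterality = obj$laterality,
      provenance = obj$provenance,
      landmarks = list(upperZ = obj$landmarks$upper_z_mm,
                       lowerZ = obj$landmarks$lower_z_mm,
                       ipsiX = obj$landmarks$ipsi_x_mm,
                       contraX = obj$landmarks$contra_x_mm,
                       chamfer = chamfer))
}

#' Read a breast contour from the simplified JSON dialect
#'
#' Accepts either explicit boundaries
#' \code{{laterality, category, superior_z_mm, inferior_z_mm}} or a
#' \code{contour_points_mm} polygon list of [x, y, z] points, whose z range
#' defines the S-I extent.
#'
#' @param path .json path.
#' @return a \code{BreastContour}.
#' @export
readBreastContourJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$laterality) || is.null(obj$category))
    stopInvalid("breast contour JSON must name laterality and category")
  if (!is.null(obj$superior_z_mm) && !is.null(obj$inferior_z_mm)) {
    sup <- obj$superior_z_mm; inf <- obj$inferior_z_mm
  } else if (!is.null(obj$contour_points_mm)) {
    pts <- obj$contour_points_mm
    z <- if (is.matrix(pts)) pts[, 3] else
      vapply(pts, function(p) as.numeric(p[[3]]), 0)
    sup <- max(z); inf <- min(z)
  } else {
    stopInvalid("breast contour JSON needs superior/inferior_z_mm or contour_points_mm")
  }
  breastContourSpec(sup, inf, obj$laterality, obj$category)
}

#' Write a breast contour in the simplified JSON dialect
#'
#' @param contour a \code{BreastContour}.
#' @param path output .json path.
#' @return \code{path}, invisibly.
#' @export
writeBreastContourJson <- function(contour, path) {
  jsonlite::write_json(list(laterality = contour@laterality,
                            category = contour@category,
                            superior_z_mm = contour@superiorZMm,
                            inferior_z_mm = contour@inferiorZMm),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a body silhouette as JSON
#'
#' Row-major 0/1 mask plus grid geometry.
#'
#' @param silhouette a \code{BodySilhouette} (or \code{CoronalMask}).
#' @param path output .json path.
#' @return \code{path}, invisibly.
#' @export
writeSilhouetteJson <- function(silhouette, path) {
  jsonlite::write_json(list(dim = dim(silhouette@mask),
                            mask = as.integer(t(silhouette@mask)),
                            spacing_mm = silhouette@spacingMm,
                            origin_mm = silhouette@originMm),
                       path, digits = NA)
  invisible(path)
}

#' Read a body silhouette from JSON
#'
#' @param path .json path written by \code{\link{writeSilhouetteJson}}.
#' @return a \code{BodySilhouette}.
#' @export
readSilhouetteJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.logical(o$mask), nrow = o$dim[1], byrow = TRUE)
  new("BodySilhouette", mask = m, spacingMm = as.numeric(o$spacing_mm),
      originMm = as.numeric(o$origin_mm))
}

#' Write a dataset to disk
#'
#' One lossless grayscale PNG per image plus a JSON sidecar with the label
#' coordinates, spacing, crop origin and seed, and a manifest with the
#' train/validation split.
#'
#' @param dataset a \code{SyntheticDataset}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset@samples)) {
    s <- dataset@samples[[i]]
    png::writePNG(s$image@pixels, file.path(dir, sprintf("img_%05d.png", i)))
    jsonlite::write_json(
      list(joints_px = lapply(targetJointNames(), function(j)
             unname(s$label@coords[j, ])),
           joint_names = targetJointNames(),
           pixel_spacing_mm = s$image@pixelSpacingMm,
           crop_origin_mm = s$image@cropOriginMm,
           seed = s$image@sourceSeed),
      file.path(dir, sprintf("img_%05d.json", i)), digits = NA)
  }
  jsonlite::write_json(list(n = length(dataset@samples), ratio = dataset@ratio,
                            seed = dataset@seed, train = dataset@trainIdx,
                            validation = dataset@validIdx),
                       file.path(dir, "manifest.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dataset from disk
#'
#' @param dir directory written by \code{\link{writeDataset}}.
#' @return a \code{SyntheticDataset}.
#' @export
readDataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  samples <- vector("list", man$n)
  for (i in seq_len(man$n)) {
    px <- png::readPNG(file.path(dir, sprintf("img_%05d.png", i)))
    if (length(dim(px)) == 3) px <- px[, , 1]
    side <- jsonlite::read_json(file.path(dir, sprintf("img_%05d.json", i)),
                                simplifyVector = TRUE)
    co <- if (is.matrix(side$joints_px)) side$joints_px else
      matrix(unlist(side$joints_px), ncol = 2, byrow = TRUE)
    dimnames(co) <- list(side$joint_names, c("row", "col"))
    samples[[i]] <- list(
      image = new("CoronalImage", pixels = px,
                  pixelSpacingMm = side$pixel_spacing_mm,
                  cropOriginMm = side$crop_origin_mm,
                  sourceSeed = as.integer(side$seed)),
      label = new("JointLabel2D", coords = co, imageSize = dim(px)))
  }
  new("SyntheticDataset", samples = samples,
      trainIdx = as.integer(man$train), validIdx = as.integer(man$validation),
      ratio = man$ratio, seed = as.integer(man$seed))
}

#' Save a trained model checkpoint
#'
#' Single-file JSON checkpoint with a versioned header.
#'
#' @param model a \code{JointPredictor}.
#' @param path output .json path.
#' @return \code{path}, invisibly.
#' @export
saveJointModel <- function(model, path) {
  p <- model@params
  ser <- lapply(p, function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
    else list(dim = NULL, data = as.numeric(x))
  })
  jsonlite::write_json(list(format = "sgroi-jointmodel", version = 1L,
                            backbone = model@backbone,
                            inputSize = model@inputSize,
                            params = ser,
                            trainMeta = model@trainMeta[c("epochs", "seed")]),
                       path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path .json checkpoint from \code{\link{saveJointModel}}.
#' @return a \code{JointPredictor}.
#' @export
readJointModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "sgroi-jointmodel"))
    stopInvalid("not an sgroi joint-model checkpoint")
  params <- lapply(obj$params, function(e) {
    if (!is.null(e$dim) && length(e$dim)) matrix(e$data, e$dim[1], e$dim[2])
    else e$data
  })
  params$poolSize <- as.integer(params$poolSize)
  new("JointPredictor", backbone = obj$backbone, params = params,
      inputSize = as.integer(obj$inputSize),
      trainMeta = list(epochs = as.integer(obj$trainMeta$epochs),
                       seed = as.integer(obj$trainMeta$seed),
                       validLoss = NA_real_))
}
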