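## Procedural parametric human body in the fixed arms-raised treatment pose.
## The template is a stack of elliptical cross-sections (torso, neck, head,
## legs) plus axis-following round tubes for the raised arms, with joints at
## fixed anatomical fractions of the template stature. Nominal template
## stature is 1700 mm; bodies are rescaled to a target height downstream.

TEMPLATE_STATURE_MM <- 1700

#' Construct body-shape parameters
#'
#' @param torsoWidthScale,torsoDepthScale,shoulderWidthScale,limbLengthScale
#'   multiplicative scales on the template dimensions; must lie within
#'   \code{bounds}.
#' @param rngSeed integer provenance seed recorded on the sampled body.
#' @param bounds allowed scale range (default 0.8--1.2).
#' @return a \code{ShapeParams} object.
#' @export
shapeParams <- function(torsoWidthScale = 1, torsoDepthScale = 1,
                        shoulderWidthScale = 1, limbLengthScale = 1,
                        rngSeed = 0L, bounds = c(0.8, 1.2)) {
  obj <- try(new("ShapeParams",
                 torsoWidthScale = torsoWidthScale,
                 torsoDepthScale = torsoDepthScale,
                 shoulderWidthScale = shoulderWidthScale,
                 limbLengthScale = limbLengthScale,
                 rngSeed = as.integer(rngSeed), bounds = bounds),
             silent = TRUE)
  if (inherits(obj, "try-error"))
    stopInvalid(paste("invalid shape parameters:", attr(obj, "condition")$message))
  obj
}

#' Draw randomized body-shape parameters
#'
#' Each scale is drawn independently and uniformly from \code{bounds},
#' covering the anthropometric spread of a breast-radiotherapy cohort.
#'
#' @param seed integer seed.
#' @param bounds scale range.
#' @return a \code{ShapeParams} object.
#' @export
randomShapeParams <- function(seed, bounds = c(0.8, 1.2)) {
  sc <- withSeed(seed, stats::runif(4, bounds[1], bounds[2]))
  shapeParams(sc[1], sc[2], sc[3], sc[4], rngSeed = seed, bounds = bounds)
}

## Run expr with a local RNG state; restores any pre-existing state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Closed tube of vertical elliptical cross-sections. centersZ increasing;
## ax/by per-ring semi-axes; cx/cy ring center in the transverse plane.
## Ends are capped with an apex vertex at the end-ring center, so each part
## is a closed surface.
makeEllipticTube <- function(cx, cy, centersZ, ax, by, nTheta = 24) {
  nr <- length(centersZ)
  theta <- 2 * pi * (seq_len(nTheta) - 1) / nTheta
  verts <- matrix(0, nr * nTheta + 2, 3)
  for (i in seq_len(nr)) {
    idx <- (i - 1) * nTheta + seq_len(nTheta)
    verts[idx, 1] <- cx[i] + ax[i] * cos(theta)
    verts[idx, 2] <- cy[i] + by[i] * sin(theta)
    verts[idx, 3] <- centersZ[i]
  }
  apexBot <- nr * nTheta + 1
  apexTop <- nr * nTheta + 2
  verts[apexBot, ] <- c(cx[1], cy[1], centersZ[1])
  verts[apexTop, ] <- c(cx[nr], cy[nr], centersZ[nr])
  faces <- vector("list", nr + 1)
  k <- seq_len(nTheta)
  kn <- c(seq_len(nTheta)[-1], 1L)
  for (i in seq_len(nr - 1)) {
    a <- (i - 1) * nTheta + k
    b <- (i - 1) * nTheta + kn
    c2 <- i * nTheta + k
    d <- i * nTheta + kn
    faces[[i]] <- rbind(cbind(a, b, c2), cbind(b, d, c2))
  }
  faces[[nr]] <- cbind(k, kn, apexBot)
  faces[[nr + 1]] <- cbind((nr - 1) * nTheta + kn, (nr - 1) * nTheta + k, apexTop)
  list(vertices = verts, faces = do.call(rbind, faces))
}

## Closed round tube following a 3D polyline whose axis lies in the x-z
## plane (the arm pose): ring frames built from each local tangent.
makeAxisTube <- function(points, radii, nTheta = 24) {
  nr <- nrow(points)
  tang <- rbind(points[2, ] - points[1, ],
                if (nr > 2) points[3:nr, ] - points[1:(nr - 2), ] else NULL,
                points[nr, ] - points[nr - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  verts <- matrix(0, nr * nTheta + 2, 3)
  theta <- 2 * pi * (seq_len(nTheta) - 1) / nTheta
  for (i in seq_len(nr)) {
    t <- tang[i, ]
    u <- c(t[3], 0, -t[1])            # in-plane normal (x-z plane axis)
    u <- u / sqrt(sum(u^2))
    v <- c(t[2] * u[3] - t[3] * u[2],
           t[3] * u[1] - t[1] * u[3],
           t[1] * u[2] - t[2] * u[1]) # completes the frame, points in y
    ring <- outer(cos(theta), u) * radii[i] + outer(sin(theta), v) * radii[i]
    idx <- (i - 1) * nTheta + seq_len(nTheta)
    verts[idx, ] <- sweep(ring, 2, points[i, ], "+")
  }
  apexBot <- nr * nTheta + 1; apexTop <- nr * nTheta + 2
  verts[apexBot, ] <- points[1, ]
  verts[apexTop, ] <- points[nr, ]
  k <- seq_len(nTheta); kn <- c(seq_len(nTheta)[-1], 1L)
  faces <- vector("list", nr + 1)
  for (i in seq_len(nr - 1)) {
    a <- (i - 1) * nTheta + k; b <- (i - 1) * nTheta + kn
    c2 <- i * nTheta + k; d <- i * nTheta + kn
    faces[[i]] <- rbind(cbind(a, b, c2), cbind(b, d, c2))
  }
  faces[[nr]] <- cbind(k, kn, apexBot)
  faces[[nr + 1]] <- cbind((nr - 1) * nTheta + kn, (nr - 1) * nTheta + k, apexTop)
  list(vertices = verts, faces = do.call(rbind, faces))
}

## Linear ring densification: resample (zFrac, a, b) control sections to
## rings spaced ~stepMm apart.
densify <- function(zf, a, b, H, stepMm = 30) {
  z <- zf * H
  n <- max(length(z), ceiling((max(z) - min(z)) / stepMm) + 1)
  zz <- seq(min(z), max(z), length.out = n)
  list(z = zz,
       a = stats::approx(z, a, zz)$y,
       b = stats::approx(z, b, zz)$y)
}

#' Sample a posed synthetic body
#'
#' Builds the arms-raised procedural template deformed by the given shape
#' scales. Deterministic: identical parameters give bit-identical meshes.
#' With all scales 1 this is the unmodified template.
#'
#' @param params a \code{ShapeParams} object.
#' @param nTheta points per cross-section ring.
#' @return a \code{BodyModel} in mm, feet near z = 0.
#' @export
sampleBody <- function(params, nTheta = 24) {
  if (!is(params, "ShapeParams")) stopInvalid("params must be a ShapeParams")
  validObject(params)
  H <- TEMPLATE_STATURE_MM
  tw <- params@torsoWidthScale; td <- params@torsoDepthScale
  sw <- params@shoulderWidthScale; ll <- params@limbLengthScale

  parts <- list()

  ## torso: hips to shoulder line; shoulder-region sections carry the
  ## shoulder width scale on top of the torso width scale
  tzf <- c(0.50, 0.56, 0.64, 0.72, 0.78, 0.815, 0.845)
  ta  <- c(165, 150, 155, 170, 175, 180, 165)
  tb  <- c(105, 100, 105, 115, 110, 105, 95)
  dd <- densify(tzf, ta, tb, H)
  wmul <- ifelse(dd$z / H >= 0.80, tw * sw, tw)
  parts$torso <- makeEllipticTube(rep(0, length(dd$z)), rep(0, length(dd$z)),
                                  dd$z, dd$a * wmul, dd$b * td, nTheta)

  ## neck
  nz <- c(0.845, 0.89) * H
  parts$neck <- makeEllipticTube(c(0, 0), c(0, 0), nz, c(48, 45), c(48, 45), nTheta)

  ## head: top of skull at exactly H in the template
  hzf <- c(0.885, 0.90, 0.93, 0.945, 0.97, 0.99, 1.0)
  ha  <- c(32, 55, 72, 75, 65, 42, 12)
  dd <- densify(hzf, ha, ha * 1.12, H, stepMm = 20)
  parts$head <- makeEllipticTube(rep(0, length(dd$z)), rep(10, length(dd$z)),
                                 dd$z, dd$a, dd$b, nTheta)

  ## legs: length scaled by the limb scale, hanging from the pelvis line
  lzf <- c(0.0, 0.06, 0.28, 0.42, 0.53)
  lr  <- c(55, 62, 70, 80, 88)
  pelvisTop <- 0.53 * H
  dd <- densify(lzf, lr, lr, H)
  legZ <- pelvisTop - (pelvisTop - dd$z) * ll
  for (s in c(1, -1)) {
    nm <- if (s > 0) "legL" else "legR"
    parts[[nm]] <- makeEllipticTube(rep(s * 92 * tw, length(legZ)),
                                    rep(0, length(legZ)),
                                    legZ, dd$a, dd$b, nTheta)
  }

  ## arms: upper arm abducted 40 deg from vertical, forearm folded inward
  ## over the head (74 deg from vertical) -- hands meet above the skull,
  ## the deep-inspiration breath-hold setup pose
  shoulderZ <- 0.822 * H
  shoulderX <- 180 * sw
  upLen <- 280 * ll; foreLen <- 320 * ll
  upDir <- c(sin(40 * pi / 180), 0, cos(40 * pi / 180))
  foreDir <- c(-sin(74 * pi / 180), 0, cos(74 * pi / 180))
  S <- c(shoulderX, 0, shoulderZ)
  E <- S + upLen * upDir
  Tt <- E + foreLen * foreDir
  for (s in c(1, -1)) {
    mir <- function(p) c(s * p[1], p[2], p[3])
    up <- makeAxisTube(rbind(mir(S), mir(S + 0.5 * upLen * upDir), mir(E)),
                       c(50, 45, 40), nTheta)
    fo <- makeAxisTube(rbind(mir(E), mir(E + 0.5 * foreLen * foreDir), mir(Tt)),
                       c(40, 36, 30), nTheta)
    parts[[if (s > 0) "armL" else "armR"]] <- up
    parts[[if (s > 0) "foreL" else "foreR"]] <- fo
  }

  ## assemble
  off <- 0L
  vlist <- list(); flist <- list()
  for (p in parts) {
    vlist[[length(vlist) + 1]] <- p$vertices
    flist[[length(flist) + 1]] <- p$faces + off
    off <- off + nrow(p$vertices)
  }
  V <- do.call(rbind, vlist)
  Fc <- do.call(rbind, flist)
  storage.mode(Fc) <- "integer"

  joints <- rbind(
    Head          = c(0, 10, 0.945 * H),
    Nose          = c(0, 70, 0.915 * H),
    LeftCollar    = c(70 * sw, 40, 0.835 * H),
    RightCollar   = c(-70 * sw, 40, 0.835 * H),
    LeftShoulder  = c(shoulderX, 0, shoulderZ),
    RightShoulder = c(-shoulderX, 0, shoulderZ),
    Spine2        = c(0, -40, 0.72 * H),
    Spine1        = c(0, -45, 0.635 * H),
    Pelvis        = c(0, -20, 0.53 * H))
  colnames(joints) <- c("x", "y", "z")

  new("BodyModel", vertices = V, faces = Fc, joints = joints,
      shapeSeed = params@rngSeed,
      heightMm = max(V[, 3]) - min(V[, 3]))
}

#' Uniformly rescale a body to a target superior--inferior extent
#'
#' Applies one isotropic scale factor to vertices and joints so the S-I
#' vertex extent equals \code{targetHeightMm}; all inter-joint distance
#' ratios are preserved.
#'
#' @param body a \code{BodyModel}.
#' @param targetHeightMm positive target extent in mm (the method's default
#'   working height is 1617 mm, the average US adult female stature).
#' @return the rescaled \code{BodyModel}.
#' @export
scaleToHeight <- function(body, targetHeightMm) {
  if (!is(body, "BodyModel")) stopInvalid("body must be a BodyModel")
  if (!is.numeric(targetHeightMm) || length(targetHeightMm) != 1 ||
      !is.finite(targetHeightMm) || targetHeightMm <= 0)
    stopInvalid("targetHeightMm must be a positive number")
  s <- targetHeightMm / body@heightMm
  new("BodyModel", vertices = body@vertices * s, faces = body@faces,
      joints = body@joints * s, shapeSeed = body@shapeSeed,
      heightMm = body@heightMm * s)
}
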