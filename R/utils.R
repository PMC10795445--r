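#' @useDynLib sgroi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## Patient coordinate frame used throughout the package:
##   x = patient-left positive, y = anterior positive, z = superior positive,
##   all lengths in mm. Images and masks are stored row 1 = most superior,
##   column 1 = most patient-right (radiographic front view), and their
##   origin slot holds the patient (x, z) of the CENTER of pixel [1, 1].

stopInvalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("sgroi_invalid_input", "error", "condition")))
}

stopDegenerate <- function(msg) {
  stop(errorCondition(msg, class = c("sgroi_degenerate_geometry", "error", "condition")))
}

## Deterministic per-task seed derivation from one global seed. Kept below
## 2^31 so the result is always a valid R integer.
deriveSeed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729 +
                as.numeric(salt) * 15485863) %% 2147483647)
}

## pixel [row, col] (1-based, possibly fractional) -> patient (x, z)
pixelToPatient <- function(row, col, origin, spacing) {
  cbind(x = origin[1] + (col - 1) * spacing[2],
        z = origin[2] - (row - 1) * spacing[1])
}

## patient (x, z) -> pixel [row, col] (1-based, fractional)
patientToPixel <- function(x, z, origin, spacing) {
  cbind(row = (origin[2] - z) / spacing[1] + 1,
        col = (x - origin[1]) / spacing[2] + 1)
}

## Shoelace area of a simple polygon given as an n x 2 matrix (x, z).
polygonArea <- function(poly) {
  x <- poly[, 1]; z <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * z - x * z[j])) / 2
}

targetJointNames <- function() c("LeftCollar", "RightCollar", "Spine2")
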