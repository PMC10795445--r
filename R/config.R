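## YAML run configuration. Defaults are the method's constants; unknown keys
## are rejected so typos cannot silently fall back to defaults.

#' Default run configuration
#'
#' @return nested list with sections \code{body}, \code{imaging},
#'   \code{training}, \code{shifts}, \code{evaluation}, plus global
#'   \code{seed} and \code{outputDir}.
#' @export
defaultConfig <- function() {
  list(
    body = list(scaleBounds = c(0.8, 1.2), targetHeightMm = 1617,
                projectionSpacingMm = 2.5),
    imaging = list(imageSize = 200L, nSamples = 3000L, splitRatio = 0.85,
                   maxCropRetries = 10L),
    training = list(backbone = "pool_mlp", poolSize = 20L, hidden = 64L,
                    lr = 1e-3, batchSize = 32L, epochs = 2000L, dropout = 0,
                    seed = 0L),
    shifts = list(upperShiftMm = 10, lowerShiftMm = 30, lrFraction = 0.75,
                  retractionMm = 80, breastEvalSupMm = 27, breastEvalInfMm = 12,
                  ptvSupMm = -24, ptvInfMm = 17),
    evaluation = list(gridSpacingMm = 1, candidateShiftsMm = seq(0, 45, by = 5)),
    seed = 0L,
    outputDir = ".")
}

mergeChecked <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stopInvalid(paste0("unknown config key(s): ",
                       paste0(path, bad, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stopInvalid(paste0("config section '", path, k, "' must be a mapping"))
      defaults[[k]] <- mergeChecked(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load a YAML run configuration
#'
#' Reads the file, validates it against the schema (unknown keys are an
#' error naming the keys), and fills unset values with the defaults. An
#' empty file yields the full defaults.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stopInvalid(paste("config file not found:", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(defaultConfig())
  if (!is.list(user)) stopInvalid("config must be a YAML mapping")
  mergeChecked(defaultConfig(), user)
}

#' Save a run configuration as YAML
#'
#' \code{loadConfig(saveConfig(cfg, path))} returns \code{cfg}.
#'
#' @param cfg config list.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
saveConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Shift configuration from a run configuration
#'
#' @param cfg config list (as from \code{\link{loadConfig}}).
#' @return a \code{ShiftConfig} built from the \code{shifts} section.
#' @export
shiftConfigFromConfig <- function(cfg) {
  do.call(shiftConfig, cfg$shifts)
}
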