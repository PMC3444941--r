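## Study configuration: construction, YAML round-trip, provenance hash.

#' Construct a study configuration
#'
#' All defaults trace to the modelled setup where the source literature fixes
#' them: widths 4.5/4.6 mm and 45 degree anastomosis; blood density 1050
#' kg/m^3 and viscosity 0.0035 Pa s; cardiac period 0.8 s, dt = 0.001 s,
#' three counted cycles.  Mesh level and waveform calibration defaults are
#' the package's desk-scale study conditions.
#'
#' @param geometry a \code{GeometryParams}.
#' @param fluid a \code{FluidProps}.
#' @param solver a \code{SolverConfig}.
#' @param calibration list from \code{\link{calibrationParams}}.
#' @param targetH,refineWall,qualityFloor mesh controls.
#' @param seed integer seed (reserved for randomized calibration searches).
#' @return A \code{StudyConfig}.
#' @export
studyConfig <- function(geometry = geometryParams(), fluid = fluidProps(),
                        solver = solverConfig(),
                        calibration = calibrationParams(),
                        targetH = 6e-4, refineWall = 4, qualityFloor = 0.01,
                        seed = 20120910) {
  new("StudyConfig", geometry = geometry, fluid = fluid, solver = solver,
      calibration = calibration,
      study = list(targetH = targetH, refineWall = refineWall,
                   qualityFloor = qualityFloor),
      seed = seed)
}

.geomFields <- c("dLad", "dGraft", "angle", "stenosisDegree", "lProx",
                 "lDist", "lGraft", "lSten", "xSten")
.fluidFields <- c("density", "viscosity")
.solverFields <- c("dt", "cycles", "period", "linTol", "stepTol",
                   "advectionScheme", "outputStride", "spinupCycles")
.calFields <- c("vTotal", "graftShares", "graftPulse", "graftPulseRatio",
                "reverseDepths", "reverseWindows", "ladPulseRatio",
                "period", "nHarmonics")
.studyFields <- c("targetH", "refineWall", "qualityFloor")

.checkKeys <- function(given, allowed, section) {
  bad <- setdiff(names(given), allowed)
  if (length(bad))
    stop(sprintf("unknown configuration key%s in [%s]: %s",
                 if (length(bad) > 1) "s" else "", section,
                 paste(bad, collapse = ", ")))
}

#' Load a study configuration from a YAML file
#'
#' Missing sections and keys fall back to the defaults of
#' \code{\link{studyConfig}}; unknown keys are rejected with an error naming
#' the key.  An empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return A validated \code{StudyConfig}.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  .checkKeys(raw, c("geometry", "fluid", "solver", "calibration", "study",
                    "seed"), "top level")
  g <- raw$geometry %||% list()
  .checkKeys(g, .geomFields, "geometry")
  geometry <- do.call(geometryParams, g[intersect(names(g), .geomFields)])
  f <- raw$fluid %||% list()
  .checkKeys(f, .fluidFields, "fluid")
  fluid <- do.call(fluidProps, f)
  s <- raw$solver %||% list()
  .checkKeys(s, .solverFields, "solver")
  solver <- do.call(solverConfig, s)
  cl <- raw$calibration %||% list()
  .checkKeys(cl, .calFields, "calibration")
  if (!is.null(cl$reverseWindows))
    cl$reverseWindows <- do.call(rbind, cl$reverseWindows)
  naify <- function(x) { x[vapply(x, is.character, TRUE) & x == "NA"] <- NA
                         as.numeric(x) }
  for (k in c("graftPulse", "graftPulseRatio"))
    if (!is.null(cl[[k]])) cl[[k]] <- naify(cl[[k]])
  calibration <- do.call(calibrationParams, cl)
  st <- raw$study %||% list()
  .checkKeys(st, .studyFields, "study")
  args <- c(list(geometry = geometry, fluid = fluid, solver = solver,
                 calibration = calibration), st)
  if (!is.null(raw$seed)) args$seed <- raw$seed
  do.call(studyConfig, args)
}

#' Save a study configuration to YAML
#'
#' Writes every parameter so that \code{\link{loadConfig}} reproduces the
#' configuration exactly.
#'
#' @param config a \code{StudyConfig}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
saveConfig <- function(config, path) {
  g <- config@geometry
  lst <- list(
    geometry = stats::setNames(lapply(.geomFields, function(f) slot(g, f)),
                               .geomFields),
    fluid = list(density = config@fluid@density,
                 viscosity = config@fluid@viscosity),
    solver = stats::setNames(lapply(.solverFields,
                                    function(f) slot(config@solver, f)),
                             .solverFields),
    calibration = local({
      cl <- config@calibration
      cl$reverseWindows <- lapply(seq_len(nrow(cl$reverseWindows)),
                                  function(i) cl$reverseWindows[i, ])
      cl
    }),
    study = config@study,
    seed = config@seed)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Deterministic configuration hash (provenance)
#' @param config a \code{StudyConfig}.
#' @return md5 hex string of the serialized configuration.
#' @export
configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveConfig(config, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
setMethod("show", "StudyConfig", function(object) {
  cat("StudyConfig:\n")
  cat(sprintf("  geometry: LAD %.3g mm / graft %.3g mm, angle %g deg\n",
              1e3 * object@geometry@dLad, 1e3 * object@geometry@dGraft,
              object@geometry@angle))
  cat(sprintf("  fluid: rho %g kg/m^3, mu %g Pa s\n",
              object@fluid@density, object@fluid@viscosity))
  cat(sprintf("  solver: dt %g s, %g cycles of %g s\n",
              object@solver@dt, object@solver@cycles, object@solver@period))
  cat(sprintf("  mesh: target h %g m, wall refinement %g\n",
              object@study$targetH, object@study$refineWall))
})
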