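#' Signed percent change
#' @param value metric for a condition.
#' @param reference metric for the reference condition (nonzero).
#' @return 100 * (value - reference) / reference.
#' @export
percentChange <- function(value, reference) {
  if (any(reference == 0)) stop("zero reference in percent change")
  100 * (value - reference) / reference
}

#' Run the five-condition competitive-flow study
#'
#' Meshes the bypass geometry once per stenosis degree, simulates each
#' canonical condition over the configured cardiac cycles, extracts TAWSS and
#' OSI, and assembles the comparison against the no-competitive-flow (full
#' occlusion) reference: percent changes of the graft-wall mean TAWSS/OSI,
#' monotone trend verdicts, the near-equivalence check for the 75% stenosis
#' condition, and the reverse distal outflow check.  Graft metrics aggregate
#' over \code{GRAFT_WALL}, which excludes the anastomosis sub-region where
#' the paper-style local extremes (toe/bed) would dominate; maxima are
#' reported separately.
#'
#' @param config a \code{StudyConfig} (see \code{\link{studyConfig}}).
#' @param verbose print progress.
#' @return A \code{StudyResult}.
#' @export
runStudy <- function(config = studyConfig(), verbose = FALSE) {
  stopifnot(is(config, "StudyConfig"))
  conds <- canonicalConditions(config@calibration,
                               dLad = config@geometry@dLad,
                               dGraft = config@geometry@dGraft)
  props <- config@fluid
  metrics <- list(); rows <- list()
  outletRev <- logical(length(conds))
  perrs <- list()
  for (i in seq_along(conds)) {
    cond <- conds[[i]]
    if (verbose) message(sprintf("condition '%s' (stenosis %.0f%%)",
                                 cond@name, 100 * cond@stenosisDegree))
    p <- config@geometry
    p@stenosisDegree <- cond@stenosisDegree
    mesh <- generateMesh(buildGeometry(p), targetH = config@study$targetH,
                         refineWall = config@study$refineWall,
                         qualityFloor = config@study$qualityFloor)
    sol <- tryCatch(
      runSimulation(mesh, cond, props, config@solver, verbose = verbose),
      error = function(e) stop(sprintf("condition '%s' failed: %s",
                                       cond@name, conditionMessage(e))))
    met <- hemodynamicMetrics(sol, cond, props)
    metrics[[cond@name]] <- met
    perrs[[cond@name]] <- sol@periodicityError
    gw <- met@summary[met@summary$region == "GRAFT_WALL", ]
    outletRev[i] <- distalOutletReverses(sol)
    rows[[i]] <- data.frame(
      condition = cond@name, stenosis = cond@stenosisDegree,
      graftMeanTAWSS = gw$meanTAWSS, graftMeanOSI = gw$meanOSI,
      graftMaxTAWSS = gw$maxTAWSS, graftMaxOSI = gw$maxOSI,
      tau0 = met@tau0, reynoldsMax = met@reynoldsMax,
      periodicityP = sol@periodicityError$pressure,
      periodicityWSS = sol@periodicityError$wss,
      outletReverses = outletRev[i])
  }
  cmp <- do.call(rbind, rows)
  ref <- cmp[cmp$condition == "none", ]
  cmp$pctTAWSS <- percentChange(cmp$graftMeanTAWSS, ref$graftMeanTAWSS)
  cmp$pctOSI <- percentChange(cmp$graftMeanOSI, ref$graftMeanOSI)
  nonRef <- cmp$condition != "none"
  slight <- {
    i75 <- which(cmp$condition == "lower")
    all(abs(cmp$pctTAWSS[i75]) <= min(abs(cmp$pctTAWSS[nonRef]))) &&
      all(abs(cmp$pctOSI[i75]) <= min(abs(cmp$pctOSI[nonRef])))
  }
  trends <- list(
    tawssIncreasing = all(diff(cmp$graftMeanTAWSS) > 0),
    osiDecreasing = all(diff(cmp$graftMeanOSI) < 0),
    slightAt75 = slight,
    reverseOutletOnlyBelow50 =
      all(outletRev[cmp$stenosis < 0.5]) && !any(outletRev[cmp$stenosis >= 0.5]))
  new("StudyResult", metrics = metrics, comparison = cmp, trends = trends,
      provenance = list(
        targetH = config@study$targetH, refineWall = config@study$refineWall,
        cycles = config@solver@cycles, dt = config@solver@dt,
        seed = config@seed,
        packageVersion = as.character(utils::packageVersion("graftflow")),
        configHash = configHash(config)))
}

## Does the distal LAD outlet carry net reverse (inward) flow at any stored
## snapshot?  The outlet flux equals (by the solver's mass closure) the sum
## of the instantaneous inflows, so this detects the propagation of graft
## reverse flow into the distal LAD.
distalOutletReverses <- function(sol) {
  mesh <- sol@mesh
  bd <- boundaryGeometry(mesh)
  sel <- which(bd$tag == "OUTLET")
  e <- bd$e[sel, , drop = FALSE]
  fluxes <- vapply(seq_along(sol@times), function(j) {
    un <- ((sol@u[e[, 1], j] + sol@u[e[, 2], j]) / 2) * bd$nx[sel] +
          ((sol@v[e[, 1], j] + sol@v[e[, 2], j]) / 2) * bd$ny[sel]
    sum(un * bd$len[sel])
  }, 0)
  any(fluxes < 0)
}

#' @export
setMethod("show", "StudyResult", function(object) {
  cat("StudyResult: five-condition competitive-flow comparison\n")
  cmp <- object@comparison
  print(cmp[, c("condition", "stenosis", "graftMeanTAWSS", "graftMeanOSI",
                "pctTAWSS", "pctOSI")], row.names = FALSE, digits = 4)
  cat("trends:",
      sprintf("TAWSS increasing: %s; OSI decreasing: %s; slight at 75%%: %s; reverse outlet only <50%%: %s\n",
              object@trends$tawssIncreasing, object@trends$osiDecreasing,
              object@trends$slightAt75, object@trends$reverseOutletOnlyBelow50))
})

#' Write the study report
#'
#' Writes the comparison table, per-condition pointwise metric tables, and a
#' plain-text summary stating the 2D-reduction caveat and configuration
#' provenance.
#'
#' @param result a \code{StudyResult}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
studyReport <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  f <- file.path(dir, "comparison.csv")
  writeCsvWithHeader(result@comparison, f,
    "five-condition comparison; stresses in Pa, lengths in m, SI units")
  paths <- c(paths, f)
  for (nm in names(result@metrics)) {
    f <- file.path(dir, sprintf("metrics_%s.csv", nm))
    writeCsvWithHeader(result@metrics[[nm]]@pointwise, f,
      "pointwise wall metrics; s = arc length (m), tawss (Pa), osi (-)")
    paths <- c(paths, f)
  }
  f <- file.path(dir, "report.txt")
  con <- file(f, "w")
  writeLines(c(
    "Competitive-flow study report",
    "=============================",
    "Model: 2D planar channel reduction of the ITA-LAD end-to-side bypass;",
    "vessel diameters are represented as channel widths, so absolute stress",
    "levels are calibrated analogues, not 3D predictions.",
    "",
    sprintf("package version: %s", result@provenance$packageVersion),
    sprintf("config hash: %s", result@provenance$configHash),
    sprintf("mesh target h: %g m (wall refinement %g)",
            result@provenance$targetH, result@provenance$refineWall),
    sprintf("cycles: %g at dt = %g s", result@provenance$cycles,
            result@provenance$dt),
    sprintf("seed: %d", result@provenance$seed),
    "",
    sprintf("max Reynolds number over study: %.1f",
            max(result@comparison$reynoldsMax)),
    sprintf("max periodicity error (pressure): %.3g%%",
            100 * max(result@comparison$periodicityP)),
    sprintf("max periodicity error (wall shear): %.3g%%",
            100 * max(result@comparison$periodicityWSS)),
    "",
    "Trend verdicts:",
    sprintf("  graft mean TAWSS strictly increasing with stenosis: %s",
            result@trends$tawssIncreasing),
    sprintf("  graft mean OSI strictly decreasing with stenosis: %s",
            result@trends$osiDecreasing),
    sprintf("  75%% stenosis closest to full occlusion (both metrics): %s",
            result@trends$slightAt75),
    sprintf("  reverse distal outflow only below 50%% stenosis: %s",
            result@trends$reverseOutletOnlyBelow50)), con)
  close(con)
  invisible(c(paths, f))
}

writeCsvWithHeader <- function(df, path, comment) {
  con <- file(path, "w")
  writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Steady mesh sensitivity analysis
#'
#' Runs the steady constant-inflow probe on the no-stenosis geometry at a
#' sequence of decreasing mesh sizes and reports successive relative changes
#' of the length-weighted mean wall shear stress and mean wall pressure,
#' flagging the coarsest level whose change from the previous level is below
#' 1% (the mesh acceptance principle).
#'
#' @param geometry a \code{GeometryParams} (stenosis is set to zero).
#' @param levels decreasing target mesh sizes (m); at least 2 for a
#'   convergence flag.
#' @param refineWall near-wall refinement factor.
#' @param props a \code{FluidProps}.
#' @param vLad,vGraft constant probe inlet velocities (m/s).
#' @param verbose print progress.
#' @return data.frame with h, nCells, meanWSS, meanP, relChangeWSS,
#'   relChangeP, converged.
#' @export
meshSensitivityReport <- function(geometry = geometryParams(),
                                  levels = c(6e-4, 3e-4, 1.5e-4),
                                  refineWall = 4, props = fluidProps(),
                                  vLad = 0.02, vGraft = 0.03,
                                  verbose = FALSE) {
  if (length(levels) >= 2 && any(diff(levels) >= 0))
    stop("levels must be strictly decreasing")
  geometry@stenosisDegree <- 0
  out <- data.frame(h = levels, nCells = NA_integer_, meanWSS = NA_real_,
                    meanP = NA_real_, relChangeWSS = NA_real_,
                    relChangeP = NA_real_, converged = NA)
  for (i in seq_along(levels)) {
    if (verbose) message(sprintf("level h = %g m", levels[i]))
    mesh <- generateMesh(buildGeometry(geometry), targetH = levels[i],
                         refineWall = refineWall)
    ss <- solveSteady(mesh, props, vLad = vLad, vGraft = vGraft)
    ops <- ss$ops
    sel <- ops$bedge$tag == "WALL"
    tw <- wallTraction(ops, ss$state$u, ss$state$v, sel)
    len <- ops$bedge$len[sel]
    out$nCells[i] <- nrow(mesh@cells)
    out$meanWSS[i] <- sum(sqrt(tw$tx^2 + tw$ty^2) * len) / sum(len)
    e <- ops$bedge$e[sel, , drop = FALSE]
    pw <- (ss$state$p[e[, 1]] + ss$state$p[e[, 2]]) / 2
    out$meanP[i] <- sum(pw * len) / sum(len)
    if (i > 1) {
      out$relChangeWSS[i] <- abs(out$meanWSS[i] - out$meanWSS[i - 1]) /
        abs(out$meanWSS[i])
      out$relChangeP[i] <- abs(out$meanP[i] - out$meanP[i - 1]) /
        max(abs(out$meanP[i]), 1e-30)
      out$converged[i] <- out$relChangeWSS[i] < 0.01
    }
  }
  out
}
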