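#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal crossprod t solve rowSums colSums
NULL

#' Parametric geometry of the planar ITA-LAD bypass model
#'
#' Describes the 2D planar idealization of an internal thoracic artery (ITA)
#' graft joined end-to-side to the left anterior descending (LAD) coronary
#' artery, with a smooth stenosis bump in the proximal LAD.  "Diameters" of the
#' original vessels become channel widths in the planar reduction.
#'
#' @slot dLad LAD channel width (m), default 4.5e-3.
#' @slot dGraft graft channel width (m), default 4.6e-3.
#' @slot angle anastomosis angle in degrees between graft and LAD axes.
#' @slot stenosisDegree fractional diameter reduction in [0, 1].
#' @slot lProx,lDist,lGraft segment lengths (m) of proximal LAD, distal LAD
#'   and graft.
#' @slot lSten stenosis bump length (m).
#' @slot xSten position (m) of the bump center along the proximal LAD.
#' @export
setClass("GeometryParams",
  representation(
    dLad = "numeric", dGraft = "numeric", angle = "numeric",
    stenosisDegree = "numeric", lProx = "numeric", lDist = "numeric",
    lGraft = "numeric", lSten = "numeric", xSten = "numeric"
  )
)

setValidity("GeometryParams", function(object) {
  msgs <- character()
  lens <- c(dLad = object@dLad, dGraft = object@dGraft, lProx = object@lProx,
            lDist = object@lDist, lGraft = object@lGraft, lSten = object@lSten,
            xSten = object@xSten)
  if (any(!is.finite(lens)) || any(lens <= 0))
    msgs <- c(msgs, "all lengths must be finite and strictly positive")
  if (!is.finite(object@stenosisDegree) ||
      object@stenosisDegree < 0 || object@stenosisDegree > 1)
    msgs <- c(msgs, "stenosisDegree must lie in [0, 1]")
  if (!is.finite(object@angle) || object@angle <= 0 || object@angle >= 90)
    msgs <- c(msgs, "angle must lie strictly between 0 and 90 degrees")
  if (length(msgs) == 0 &&
      (object@xSten - object@lSten / 2 < 0 ||
       object@xSten + object@lSten / 2 > object@lProx))
    msgs <- c(msgs, "stenosis bump must lie entirely within the proximal LAD segment")
  if (length(msgs)) msgs else TRUE
})

#' Tagged unstructured triangle mesh
#'
#' Conforming triangle discretization of the bypass domain.  Boundary edges
#' carry exactly one tag from \code{LAD_INLET}, \code{GRAFT_INLET},
#' \code{OUTLET}, \code{WALL}; wall edges additionally carry a region sub-tag
#' (\code{LAD_WALL_PROX}, \code{LAD_WALL_DIST}, \code{GRAFT_WALL},
#' \code{ANASTOMOSIS}) used when aggregating wall metrics.
#'
#' @slot nodes n x 2 matrix of coordinates (m).
#' @slot cells m x 3 integer matrix of node indices (1-based, positively
#'   oriented).
#' @slot boundaryEdges k x 2 integer matrix of boundary edge node pairs.
#' @slot boundaryTag character vector of length k.
#' @slot wallRegion character vector of length k (\code{NA} off walls).
#' @slot meta list of construction metadata (geometry parameters, target size,
#'   junction coordinates).
#' @export
setClass("TriMesh",
  representation(
    nodes = "matrix", cells = "matrix", boundaryEdges = "matrix",
    boundaryTag = "character", wallRegion = "character", meta = "list"
  )
)

setValidity("TriMesh", function(object) {
  msgs <- character()
  n <- nrow(object@nodes)
  if (ncol(object@nodes) != 2) msgs <- c(msgs, "nodes must be n x 2")
  if (ncol(object@cells) != 3) msgs <- c(msgs, "cells must be m x 3")
  if (nrow(object@boundaryEdges) != length(object@boundaryTag))
    msgs <- c(msgs, "one tag per boundary edge required")
  if (length(object@wallRegion) != length(object@boundaryTag))
    msgs <- c(msgs, "one wallRegion entry per boundary edge required")
  if (length(msgs) == 0) {
    if (max(object@cells) > n || min(object@cells) < 1)
      msgs <- c(msgs, "cell connectivity out of range")
    bad <- !(object@boundaryTag %in%
               c("LAD_INLET", "GRAFT_INLET", "OUTLET", "WALL"))
    if (any(bad)) msgs <- c(msgs, "unknown boundary tag")
    ## closed boundary: every boundary node appears in exactly two edges
    deg <- table(as.vector(object@boundaryEdges))
    if (any(deg != 2)) msgs <- c(msgs, "boundary is not closed (node degree != 2)")
    a <- triangleAreas(object@nodes, object@cells)
    if (any(a <= 0)) msgs <- c(msgs, "all triangles must be positively oriented")
  }
  if (length(msgs)) msgs else TRUE
})

#' Periodic inlet velocity waveform
#'
#' A truncated Fourier representation of the cross-section-mean inlet velocity
#' v(t) over one cardiac cycle.  The constant term equals the cycle mean
#' exactly, so the declared mean is reproduced to machine precision by the
#' closed-form series.
#'
#' @slot period cycle duration (s).
#' @slot meanVelocity cycle-mean velocity (m/s), equals the constant Fourier
#'   term.
#' @slot cosCoef,sinCoef harmonic coefficients (m/s); harmonic k has angular
#'   frequency 2*pi*k/period.
#' @slot reverseWindows numeric matrix (possibly 0-row) of [start, end] time
#'   intervals targeted for reverse flow during construction.
#' @export
setClass("Waveform",
  representation(
    period = "numeric", meanVelocity = "numeric",
    cosCoef = "numeric", sinCoef = "numeric", reverseWindows = "matrix"
  )
)

setValidity("Waveform", function(object) {
  msgs <- character()
  if (object@period <= 0) msgs <- c(msgs, "period must be positive")
  if (length(object@cosCoef) != length(object@sinCoef))
    msgs <- c(msgs, "cosCoef and sinCoef must have equal length")
  if (nrow(object@reverseWindows) > 0 && ncol(object@reverseWindows) != 2)
    msgs <- c(msgs, "reverseWindows must have two columns")
  if (length(msgs)) msgs else TRUE
})

setClassUnion("WaveformOrNULL", c("Waveform", "NULL"))

#' One competitive-flow condition
#'
#' Pairs a stenosis degree with the LAD and graft inlet waveforms that define
#' one of the study's flow conditions.  The fully occluded condition has no
#' LAD waveform (the proximal inlet is walled off).
#'
#' @slot name one of "higher", "secondary", "reduced", "lower", "none".
#' @slot stenosisDegree fractional LAD diameter reduction.
#' @slot ladWaveform \code{Waveform} or \code{NULL}.
#' @slot graftWaveform \code{Waveform}.
#' @export
setClass("ConditionSpec",
  representation(
    name = "character", stenosisDegree = "numeric",
    ladWaveform = "WaveformOrNULL", graftWaveform = "Waveform"
  )
)

setValidity("ConditionSpec", function(object) {
  msgs <- character()
  if (object@stenosisDegree < 0 || object@stenosisDegree > 1)
    msgs <- c(msgs, "stenosisDegree must lie in [0, 1]")
  if (object@stenosisDegree >= 1 && !is.null(object@ladWaveform))
    msgs <- c(msgs, "fully occluded condition must not carry an LAD waveform")
  if (object@stenosisDegree < 1 && is.null(object@ladWaveform))
    msgs <- c(msgs, "non-occluded condition requires an LAD waveform")
  if (length(msgs)) msgs else TRUE
})

#' Physical properties of blood
#'
#' @slot density rho (kg/m^3), default 1050.
#' @slot viscosity dynamic viscosity mu (Pa s), default 0.0035.
#' @export
setClass("FluidProps",
  representation(density = "numeric", viscosity = "numeric"))

setValidity("FluidProps", function(object) {
  if (object@density > 0 && object@viscosity > 0) TRUE
  else "density and viscosity must be strictly positive"
})

#' Numerical controls of the transient solver
#'
#' @slot dt time step (s); must divide the period to machine precision.
#' @slot cycles counted cardiac cycles (>= 2; the last two are compared for
#'   periodicity).
#' @slot period cardiac period (s).
#' @slot linTol linear solver tolerance (direct solves: residual check bound).
#' @slot stepTol relative step-convergence tolerance for steady solves.
#' @slot advectionScheme "supg" (streamline-diffusion stabilized) or
#'   "galerkin".
#' @slot outputStride store every outputStride-th step.
#' @slot spinupCycles untracked preconditioning cycles run after the steady
#'   initialisation, before the counted cycles.
#' @export
setClass("SolverConfig",
  representation(
    dt = "numeric", cycles = "numeric", period = "numeric",
    linTol = "numeric", stepTol = "numeric", advectionScheme = "character",
    outputStride = "numeric", spinupCycles = "numeric"
  )
)

setValidity("SolverConfig", function(object) {
  msgs <- character()
  if (object@dt <= 0 || object@period <= 0)
    msgs <- c(msgs, "dt and period must be positive")
  nsteps <- object@period / object@dt
  if (abs(nsteps - round(nsteps)) > 1e-9)
    msgs <- c(msgs, "dt must divide the period")
  if (object@cycles < 2) msgs <- c(msgs, "cycles must be >= 2")
  if (!object@advectionScheme %in% c("supg", "galerkin"))
    msgs <- c(msgs, "advectionScheme must be 'supg' or 'galerkin'")
  if (object@outputStride < 1 ||
      round(nsteps) %% round(object@outputStride) != 0)
    msgs <- c(msgs, "outputStride must divide the steps per cycle")
  if (length(msgs)) msgs else TRUE
})

#' Time-resolved flow fields over the final cardiac cycle
#'
#' @slot mesh the \code{TriMesh} the solution lives on.
#' @slot times snapshot times of the final cycle (s), spanning one period
#'   inclusive of both endpoints.
#' @slot u,v n x nsnap nodal velocity components (m/s).
#' @slot p n x nsnap nodal pressures (Pa, relative to the outlet).
#' @slot wallTraces list with per-cycle wall-sampled traces (shear vector and
#'   pressure at wall edge midpoints) used for the periodicity diagnostics.
#' @slot periodicityError list(pressure =, wss =) relative L2 difference of
#'   the final vs penultimate cycle.
#' @slot diagnostics list of solver diagnostics (max divergence residual, max
#'   boundary flux imbalance, peak inlet speed, ...).
#' @export
setClass("FlowSolution",
  representation(
    mesh = "TriMesh", times = "numeric", u = "matrix", v = "matrix",
    p = "matrix", wallTraces = "list", periodicityError = "list",
    diagnostics = "list"
  )
)

#' Wall shear stress vector history along one wall region
#'
#' @slot region wall region tag.
#' @slot s arc-length coordinates (m) of wall edge midpoints.
#' @slot points midpoint coordinates (np x 2).
#' @slot normals outward unit normals (np x 2).
#' @slot times sample times spanning exactly one period.
#' @slot tauX,tauY np x nt tangential traction components (Pa).
#' @export
setClass("WallShearSeries",
  representation(
    region = "character", s = "numeric", points = "matrix",
    normals = "matrix", times = "numeric", tauX = "matrix", tauY = "matrix"
  )
)

setValidity("WallShearSeries", function(object) {
  msgs <- character()
  np <- length(object@s); nt <- length(object@times)
  if (!all(dim(object@tauX) == c(np, nt)) ||
      !all(dim(object@tauY) == c(np, nt)))
    msgs <- c(msgs, "tauX/tauY must be np x nt")
  if (nt >= 2) {
    span <- object@times[nt] - object@times[1]
    if (span <= 0) msgs <- c(msgs, "times must be increasing")
  }
  if (length(msgs)) msgs else TRUE
})

#' Derived hemodynamic indices for one condition
#'
#' @slot pointwise data.frame with columns region, s, tawss, osi.
#' @slot summary data.frame with per-region mean/max TAWSS and OSI.
#' @slot tau0 Poiseuille reference wall shear (Pa) at the graft mean flow.
#' @slot reynoldsMax maximum instantaneous Reynolds number at the graft inlet.
#' @export
setClass("HemodynamicMetrics",
  representation(
    pointwise = "data.frame", summary = "data.frame",
    tau0 = "numeric", reynoldsMax = "numeric"
  )
)

#' Result of the five-condition competitive-flow study
#'
#' @slot metrics named list of \code{HemodynamicMetrics}, one per condition in
#'   stenosis order.
#' @slot comparison data.frame of per-condition graft-wall means and percent
#'   changes relative to the no-competitive-flow condition.
#' @slot trends list of logical trend verdicts (tawssIncreasing,
#'   osiDecreasing, slightAt75, reverseOutletOnlyBelow50).
#' @slot provenance list (config hash, mesh level, package version, seed).
#' @export
setClass("StudyResult",
  representation(
    metrics = "list", comparison = "data.frame", trends = "list",
    provenance = "list"
  )
)

#' Full study configuration
#'
#' @slot geometry \code{GeometryParams} (stenosisDegree is overridden per
#'   condition by the study driver).
#' @slot fluid \code{FluidProps}.
#' @slot solver \code{SolverConfig}.
#' @slot calibration named list of waveform calibration parameters.
#' @slot study named list: targetH, refineWall, qualityFloor.
#' @slot seed integer seed (reserved for randomized calibration searches; the
#'   default pipeline is fully deterministic).
#' @export
setClass("StudyConfig",
  representation(
    geometry = "GeometryParams", fluid = "FluidProps",
    solver = "SolverConfig", calibration = "list", study = "list",
    seed = "numeric"
  )
)
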