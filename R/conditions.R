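#' Default waveform calibration parameters
#'
#' The five canonical competitive-flow conditions split a fixed total mean
#' distal perfusion between the LAD and the graft as a function of stenosis
#' degree (fixed-total-perfusion assumption).  Amplitudes were calibrated once
#' against the analytic plane-channel Womersley wall-shear transfer so that
#' the graft-wall time-averaged wall shear stress spans roughly 0.1-0.24 Pa
#' (increasing with stenosis degree) and the oscillatory shear index spans
#' roughly 0.02-0.24 (decreasing with stenosis degree), with reverse graft
#' flow at the start and end of the cycle only below 50% stenosis.
#'
#' A note on Reynolds number: with the wall-shear band fixed, the peak
#' instantaneous graft-inlet Reynolds number of the calibrated set is about
#' 230.  A calibration that instead pushes a brief velocity spike to
#' Re ~ 1050 in a 4.6 mm plane channel necessarily drives the time-averaged
#' wall shear far above the band, because the wall-shear response of harmonic
#' k grows like sqrt(k) relative to quasi-steady shear; the two figures are
#' mutually exclusive in this reduced model, and the calibration keeps the
#' band.
#'
#' @param vTotal total mean perfusion velocity scale (m/s); the total mean
#'   inflow rate held fixed across conditions is vTotal times the average of
#'   the two channel widths.
#' @param graftShares graft fraction of the total mean inflow rate per
#'   condition, in stenosis order (0, 0.30, 0.50, 0.75, 1.0).
#' @param graftPulse graft pulse amplitudes (m/s); \code{NA} entries use the
#'   pulsatility ratios instead.
#' @param graftPulseRatio pulse-to-mean ratios used where \code{graftPulse}
#'   is \code{NA}.
#' @param reverseDepths target reverse velocities (m/s) for the two reversing
#'   conditions.
#' @param reverseWindows 2-column matrix of reverse-flow time windows (s).
#' @param ladPulseRatio LAD pulse-to-mean ratio (no reversal).
#' @param period cardiac period (s).
#' @param nHarmonics Fourier harmonics per waveform.
#' @return Named list of calibration parameters.
#' @export
calibrationParams <- function(vTotal = 0.049,
                              graftShares = c(0.25, 0.40, 0.60, 0.85, 1.0),
                              graftPulse = c(0.028, 0.040, NA, NA, NA),
                              graftPulseRatio = c(NA, NA, 2.2, 1.7, 1.5),
                              reverseDepths = c(0.009, 0.006),
                              reverseWindows = rbind(c(0, 0.07), c(0.73, 0.8)),
                              ladPulseRatio = 2.2,
                              period = 0.8, nHarmonics = 32) {
  list(vTotal = vTotal, graftShares = graftShares, graftPulse = graftPulse,
       graftPulseRatio = graftPulseRatio, reverseDepths = reverseDepths,
       reverseWindows = reverseWindows, ladPulseRatio = ladPulseRatio,
       period = period, nHarmonics = nHarmonics)
}

.conditionNames <- c("higher", "secondary", "reduced", "lower", "none")
.conditionStenosis <- c(0, 0.30, 0.50, 0.75, 1.0)

#' The five canonical competitive-flow conditions
#'
#' Builds the canonical set: higher (no stenosis), secondary (30%), reduced
#' (50%), lower (75%) and no competitive flow (full occlusion).  Graft mean
#' velocity increases and LAD mean velocity decreases with stenosis degree
#' (complementary split of a fixed total mean perfusion); graft reverse-flow
#' windows at the start and end of the cycle are present only below 50%
#' stenosis; the fully occluded condition carries no LAD waveform.
#'
#' The split is applied to mean flow rates (velocity times channel width),
#' so the total mean inflow rate is identical across conditions.
#'
#' @param calibration list from \code{\link{calibrationParams}}.
#' @param dLad,dGraft channel widths (m) used to convert the rate split into
#'   mean velocities.
#' @return List of five \code{ConditionSpec} objects in stenosis order.
#' @export
canonicalConditions <- function(calibration = calibrationParams(),
                                dLad = 4.5e-3, dGraft = 4.6e-3) {
  cal <- calibration
  stopifnot(length(cal$graftShares) == 5)
  dBar <- (dLad + dGraft) / 2
  conds <- vector("list", 5)
  for (i in 1:5) {
    sDeg <- .conditionStenosis[i]
    mG <- cal$graftShares[i] * cal$vTotal * dBar / dGraft
    A <- if (is.na(cal$graftPulse[i])) cal$graftPulseRatio[i] * mG
         else cal$graftPulse[i]
    if (sDeg < 0.5) {
      wG <- makeWaveform(mG, A, reverseWindow = cal$reverseWindows,
                         period = cal$period, nHarmonics = cal$nHarmonics,
                         reverseDepth = cal$reverseDepths[i])
    } else {
      wG <- makeWaveform(mG, A, period = cal$period,
                         nHarmonics = cal$nHarmonics)
    }
    wL <- NULL
    if (sDeg < 1) {
      mL <- (1 - cal$graftShares[i]) * cal$vTotal * dBar / dLad
      wL <- makeWaveform(mL, cal$ladPulseRatio * mL, period = cal$period,
                         nHarmonics = cal$nHarmonics)
    }
    conds[[i]] <- new("ConditionSpec", name = .conditionNames[i],
                      stenosisDegree = sDeg, ladWaveform = wL,
                      graftWaveform = wG)
  }
  names(conds) <- .conditionNames
  ## calibration targets are contracts: fail loudly if they conflict
  mGs <- vapply(conds, function(cd) cd@graftWaveform@meanVelocity, 0)
  if (any(diff(mGs) <= 0))
    stop("infeasible calibration: graft mean velocities not strictly increasing")
  rev <- vapply(conds, function(cd) reverseFraction(cd@graftWaveform), 0)
  if (!all((rev > 0) == (.conditionStenosis < 0.5)))
    stop("infeasible calibration: reverse flow must occur iff stenosis < 50%")
  ladRev <- vapply(conds[1:4], function(cd) reverseFraction(cd@ladWaveform), 0)
  if (any(ladRev > 0))
    stop("infeasible calibration: LAD waveforms must not reverse")
  conds
}

#' @export
setMethod("show", "ConditionSpec", function(object) {
  cat(sprintf("ConditionSpec '%s': stenosis %.0f%%\n", object@name,
              100 * object@stenosisDegree))
  cat("  graft: "); show(object@graftWaveform)
  if (is.null(object@ladWaveform)) {
    cat("  LAD inlet: walled off (full occlusion)\n")
  } else {
    cat("  LAD:   "); show(object@ladWaveform)
  }
})

#' Fluid properties constructor
#' @param density blood density (kg/m^3).
#' @param viscosity dynamic viscosity (Pa s).
#' @return A \code{FluidProps}.
#' @export
fluidProps <- function(density = 1050, viscosity = 0.0035) {
  new("FluidProps", density = density, viscosity = viscosity)
}

#' Solver configuration constructor
#' @param dt time step (s).
#' @param cycles counted cardiac cycles.
#' @param period cardiac period (s).
#' @param linTol linear residual bound.
#' @param stepTol steady-state relative increment tolerance.
#' @param advectionScheme "supg" or "galerkin".
#' @param outputStride snapshot stride.
#' @param spinupCycles preconditioning cycles before the counted ones.
#' @return A \code{SolverConfig}.
#' @export
solverConfig <- function(dt = 0.001, cycles = 3, period = 0.8,
                         linTol = 1e-8, stepTol = 1e-6,
                         advectionScheme = "supg", outputStride = 4,
                         spinupCycles = 1) {
  new("SolverConfig", dt = dt, cycles = cycles, period = period,
      linTol = linTol, stepTol = stepTol, advectionScheme = advectionScheme,
      outputStride = outputStride, spinupCycles = spinupCycles)
}
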