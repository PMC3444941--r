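## Closed-form oscillatory plane-channel (2D Womersley) flow.
##
## For a channel of width H driven so that the cross-section-mean velocity is
## v(t) = Re sum_k U_k exp(i k w t), the velocity profile of harmonic k is
##   u_k(yhat) = U_k (1 - cosh(L yhat)/cosh(L)) / (1 - tanh(L)/L),
## with yhat = 2y/H - 1 in [-1, 1] and L = alpha_k sqrt(i),
## alpha_k = (H/2) sqrt(k w rho / mu).  The steady harmonic is the parabola
## 1.5 U_0 (1 - yhat^2).  Wall shear follows by differentiation at yhat = -1.

#' Womersley number
#'
#' alpha = R sqrt(omega rho / mu) with R the channel half-width.
#'
#' @param R half-width (m).
#' @param omega angular frequency (rad/s).
#' @param props a \code{FluidProps}.
#' @return Dimensionless Womersley number.
#' @export
womersleyAlpha <- function(R, omega, props) {
  R * sqrt(omega * props@density / props@viscosity)
}

## Complex profile factor and wall-shear factor for one harmonic.
.womFactors <- function(alpha) {
  L <- alpha * complex(real = 1 / sqrt(2), imaginary = 1 / sqrt(2))
  denom <- 1 - tanh(L) / L
  list(L = L, denom = denom)
}

#' Analytic oscillatory channel velocity profile
#'
#' Evaluates the closed-form pulsatile plane-channel solution whose
#' cross-section-mean velocity equals the given waveform.
#'
#' @param w a \code{Waveform} (cross-section-mean velocity).
#' @param y cross-channel coordinates (m), 0 and \code{width} at the walls.
#' @param t time (s), scalar.
#' @param width channel width (m).
#' @param props a \code{FluidProps}.
#' @return Velocities u(y, t) (m/s), same length as \code{y}.
#' @export
womersleyProfile <- function(w, y, t, width, props) {
  yhat <- 2 * y / width - 1
  omega <- 2 * pi / w@period
  u <- w@meanVelocity * 1.5 * (1 - yhat^2)
  for (k in seq_along(w@cosCoef)) {
    Uk <- complex(real = w@cosCoef[k], imaginary = -w@sinCoef[k])
    if (Mod(Uk) == 0) next
    alpha <- womersleyAlpha(width / 2, k * omega, props)
    fac <- .womFactors(alpha)
    prof <- (1 - cosh(fac$L * yhat) / cosh(fac$L)) / fac$denom
    u <- u + Re(Uk * prof * exp(complex(imaginary = k * omega * t)))
  }
  u
}

#' Analytic oscillatory channel wall shear
#'
#' Wall shear stress history tau(t) = mu du/dy at the wall for the pulsatile
#' plane-channel flow whose mean velocity is the given waveform.  Used as the
#' quasi-analytic transfer from an inlet waveform to fully developed wall
#' shear (each harmonic is attenuated and phase-shifted by the Womersley
#' factor L tanh(L) / (1 - tanh(L)/L)).
#'
#' @param w a \code{Waveform}.
#' @param t times (s).
#' @param width channel width (m).
#' @param props a \code{FluidProps}.
#' @return Wall shear stresses (Pa), signed along the flow direction.
#' @export
womersleyWallShear <- function(w, t, width, props) {
  mu <- props@viscosity
  omega <- 2 * pi / w@period
  tau <- rep(6 * mu * w@meanVelocity / width, length(t))
  for (k in seq_along(w@cosCoef)) {
    Uk <- complex(real = w@cosCoef[k], imaginary = -w@sinCoef[k])
    if (Mod(Uk) == 0) next
    alpha <- womersleyAlpha(width / 2, k * omega, props)
    fac <- .womFactors(alpha)
    tauk <- mu * Uk * (2 / width) * fac$L * tanh(fac$L) / fac$denom
    tau <- tau + Re(tauk * exp(complex(imaginary = outer(k * omega, t)[1, ])))
  }
  tau
}

#' Pulsatile solver validation against the analytic channel solution
#'
#' Drives a straight channel with the exact oscillatory (Womersley) velocity
#' profile at the inlet, integrates the transient solver over settling plus
#' one comparison period, and reports the maximum relative deviation of the
#' mid-channel velocity profile from the closed form over the cycle
#' (normalized by the peak analytic speed).
#'
#' @param mesh channel mesh from \code{\link{channelMesh}} (default: LAD-width
#'   channel at 0.3 mm resolution).
#' @param vMean mean velocity (m/s) of the driving waveform.
#' @param amp first-harmonic amplitude (m/s).
#' @param props a \code{FluidProps}.
#' @param config a \code{SolverConfig}; \code{cycles} counts settling + 1.
#' @return list(maxRelError, alpha, times).
#' @export
womersleyBenchmark <- function(mesh = channelMesh(4.5e-3, 0.012, 3e-4),
                               vMean = 0.0, amp = 0.03,
                               props = fluidProps(),
                               config = solverConfig(cycles = 2,
                                                     spinupCycles = 0)) {
  if (!"LAD_INLET" %in% mesh@boundaryTag || "GRAFT_INLET" %in% mesh@boundaryTag)
    stop("womersleyBenchmark needs a straight channel mesh")
  H <- mesh@meta$width
  w <- new("Waveform", period = config@period, meanVelocity = vMean,
           cosCoef = c(0, numeric(7)), sinCoef = c(amp, numeric(7)),
           reverseWindows = matrix(numeric(0), 0, 2))
  ops <- assembleOperators(mesh, props)
  geo <- inletGeometry(mesh, "LAD_INLET")
  yIn <- mesh@nodes[geo$nodes, 2]
  wallNodes <- setdiff(ops$dirNodes, geo$nodes)
  bcs <- function(t) {
    prof <- womersleyProfile(w, yIn, t, H, props)
    list(nodes = c(wallNodes, geo$nodes),
         ux = c(numeric(length(wallNodes)), prof),
         uy = numeric(length(wallNodes) + length(geo$nodes)))
  }
  ## initialize with the analytic field (x-independent)
  state <- newFlowState(ops)
  state$u <- womersleyProfile(w, mesh@nodes[, 2], 0, H, props)
  state$u[ops$dirNodes] <- 0
  state$u[geo$nodes] <- womersleyProfile(w, yIn, 0, H, props)
  nsteps <- round(config@period / config@dt)
  stride <- round(config@outputStride)
  nset <- (round(config@cycles) - 1) * nsteps
  t <- 0
  for (k in seq_len(nset)) {
    state <- stepFlow(state, t, bcs, config, ops)
    t <- t + config@dt
  }
  xmid <- mesh@meta$length / 2
  midSel <- abs(mesh@nodes[, 1] - xmid) < mesh@meta$length / (2 * 40)
  midSel <- which(midSel)
  if (!length(midSel)) midSel <- which.min(abs(mesh@nodes[, 1] - xmid))
  yMid <- mesh@nodes[midSel, 2]
  peakAna <- 0; errMax <- 0; times <- numeric(0)
  for (k in seq_len(nsteps)) {
    state <- stepFlow(state, t, bcs, config, ops)
    t <- t + config@dt
    if (k %% stride == 0) {
      ana <- womersleyProfile(w, yMid, t, H, props)
      peakAna <- max(peakAna, abs(ana))
      errMax <- max(errMax, max(abs(state$u[midSel] - ana)))
      times <- c(times, t)
    }
  }
  list(maxRelError = errMax / peakAna,
       alpha = womersleyAlpha(H / 2, 2 * pi / config@period, props),
       times = times)
}
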