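## Transient incompressible Navier-Stokes time stepping.
##
## Scheme: incremental pressure-correction projection on P1/P1 triangles.
## Momentum: backward-Euler in time with implicit viscosity and implicitly
## treated convection linearized about the AB2-extrapolated velocity
## (2 u^n - u^{n-1}), plus streamline-diffusion stabilization; the momentum
## matrix is shared by both velocity components and LU-factorized once per
## step.  Projection (pressure increment zero at the outlet): a smooth P1
## Laplacian Poisson solve followed by an exact discrete projection
## B = D M_L^{-1} D^t that removes the residual weak divergence the smooth
## solve cannot reach; both increments accumulate into the working pressure
## (exact steady fixed point), while the smooth accumulation alone is what
## snapshots and wall traces report.  A final outlet flux correction closes
## the global mass balance exactly.  Unconditionally stable at the fixed
## dt = 0.001 s.

#' Create a zero flow state
#' @param ops operator set from \code{\link{assembleOperators}}.
#' @return list with velocity and pressure vectors at rest.
#' @export
newFlowState <- function(ops) {
  z <- numeric(ops$n)
  list(u = z, v = z, p = z, pB = z, pOut = z, uPrev = NULL, vPrev = NULL, bcPeak = 0,
       divResidual = 0, fluxImbalance = 0)
}

#' Advance the flow one time step
#'
#' @param state flow state (from \code{\link{newFlowState}} or a previous
#'   step).
#' @param t current time (s); the step advances to t + dt.
#' @param bcs callable: \code{bcs(t)} returns
#'   \code{list(nodes =, ux =, uy =)} with Dirichlet velocity values (walls
#'   and inlets).
#' @param config a \code{SolverConfig}.
#' @param ops operator set for the mesh.
#' @return The next state; components divResidual (weak divergence at
#'   enforced interior pressure nodes, m^2/s) and fluxImbalance (net boundary
#'   flux after mass closure, m^2/s).
#' @export
stepFlow <- function(state, t, bcs, config, ops) {
  dt <- config@dt
  supg <- config@advectionScheme == "supg"
  wx <- if (is.null(state$uPrev)) state$u else 2 * state$u - state$uPrev
  wy <- if (is.null(state$vPrev)) state$v else 2 * state$v - state$vPrev
  Ax <- momentumMatrixX(ops, wx, wy, dt, supg)
  rhoMdt <- ops$rho * ops$MLgeo / dt
  rhsU <- rhoMdt * state$u + as.vector(Matrix::t(ops$Dx) %*% state$p)
  rhsV <- rhoMdt * state$v + as.vector(Matrix::t(ops$Dy) %*% state$p)
  g <- bcs(t + dt)
  gU <- numeric(ops$n); gV <- numeric(ops$n)
  gU[g$nodes] <- g$ux; gV[g$nodes] <- g$uy
  A <- ops$Atmpl; A@x <- Ax
  ru <- (rhsU - as.vector(A %*% gU))[ops$freeU]
  rv <- (rhsV - as.vector(A %*% gV))[ops$freeU]
  Aff <- ops$AffTmpl; Aff@x <- Ax[ops$mapFF]
  lufac <- Matrix::lu(Aff)
  uf <- as.vector(Matrix::solve(lufac, ru))
  vf <- as.vector(Matrix::solve(lufac, rv))
  us <- gU; vs <- gV
  us[ops$freeU] <- uf; vs[ops$freeU] <- vf

  ## pressure increment from the smooth (Laplacian) pressure Poisson solve,
  ## zero at the outlet
  applyCorrection <- function(u0, v0, phi) {
    gpx <- as.vector(Matrix::t(ops$Dx) %*% phi)
    gpy <- as.vector(Matrix::t(ops$Dy) %*% phi)
    u0[ops$freeU] <- u0[ops$freeU] +
      (dt / ops$rho) * gpx[ops$freeU] / ops$MLgeo[ops$freeU]
    v0[ops$freeU] <- v0[ops$freeU] +
      (dt / ops$rho) * gpy[ops$freeU] / ops$MLgeo[ops$freeU]
    list(u = u0, v = v0)
  }
  div <- as.vector(ops$Dx %*% us + ops$Dy %*% vs)
  phi <- numeric(ops$n)
  phi[ops$pFree] <- as.vector(
    Matrix::solve(ops$Lchol, -(ops$rho / dt) * div[ops$pFree]))
  cor1 <- applyCorrection(us, vs, phi)
  ## exact-projection cleanup: kills the residual discrete divergence the
  ## smooth solve cannot reach (its right-hand side is orthogonal to B's
  ## checkerboard null space, so the increment stays bounded); both
  ## increments accumulate into the working pressure so the scheme has an
  ## exact steady fixed point, while the smooth part alone is reported
  div1 <- as.vector(ops$Dx %*% cor1$u + ops$Dy %*% cor1$v)
  phiB <- numeric(ops$n)
  phiB[ops$pFree] <- as.vector(
    Matrix::solve(ops$Bchol, -(ops$rho / dt) * div1[ops$pFree]))
  cor2 <- applyCorrection(cor1$u, cor1$v, phiB)
  un <- cor2$u; vn <- cor2$v
  pn <- state$p + phi + phiB
  pBn <- (state$pB %||% 0) + phiB

  ## global mass closure through the outlet
  if (abs(ops$outletUnitFlux) > 0) {
    F0 <- boundaryFlux(ops, un, vn)
    un[ops$outletNodes] <- un[ops$outletNodes] - F0 / ops$outletUnitFlux
  }

  bcPeak <- max(state$bcPeak, abs(g$ux), abs(g$uy))
  speed <- max(abs(un), abs(vn))
  if (!is.finite(speed) || speed > 100 * max(bcPeak, 1e-9))
    stop(sprintf("divergence failure at t = %.4f s (velocity blow-up)", t + dt))
  div2 <- as.vector(ops$Dx %*% un + ops$Dy %*% vn)
  dres <- if (length(ops$divCheckNodes)) max(abs(div2[ops$divCheckNodes])) else 0
  list(u = un, v = vn, p = pn, pB = pBn, pOut = pn - pBn,
       uPrev = state$u, vPrev = state$v,
       bcPeak = bcPeak, divResidual = dres,
       fluxImbalance = boundaryFlux(ops, un, vn))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kinetic energy of a flow state
#' @param ops operator set.
#' @param state flow state.
#' @return 0.5 rho integral of |u|^2 (J/m, per unit out-of-plane depth).
#' @export
kineticEnergy <- function(ops, state) {
  0.5 * ops$rho * sum(ops$MLgeo * (state$u^2 + state$v^2))
}

## Dirichlet boundary closure for a condition: no-slip walls + pulsatile
## parabolic inlet profiles.
conditionBC <- function(ops, condition) {
  mesh <- ops$mesh
  wallNodes <- setdiff(ops$dirNodes, integer(0))
  hasLad <- "LAD_INLET" %in% mesh@boundaryTag
  if (hasLad && is.null(condition@ladWaveform))
    stop("mesh has an LAD inlet but the condition has no LAD waveform")
  ladGeo <- if (hasLad) inletGeometry(mesh, "LAD_INLET") else NULL
  graftGeo <- inletGeometry(mesh, "GRAFT_INLET")
  function(t) {
    ux <- numeric(length(wallNodes)); uy <- ux
    nodes <- wallNodes
    if (hasLad) {
      vm <- waveformVelocity(condition@ladWaveform, t)
      mag <- 6 * vm * ladGeo$zeta * (1 - ladGeo$zeta)
      nodes <- c(nodes, ladGeo$nodes)
      ux <- c(ux, mag * ladGeo$dir[1]); uy <- c(uy, mag * ladGeo$dir[2])
    }
    vg <- waveformVelocity(condition@graftWaveform, t)
    magg <- 6 * vg * graftGeo$zeta * (1 - graftGeo$zeta)
    nodes <- c(nodes, graftGeo$nodes)
    ux <- c(ux, magg * graftGeo$dir[1]); uy <- c(uy, magg * graftGeo$dir[2])
    list(nodes = nodes, ux = ux, uy = uy)
  }
}

## Pseudo-time march to steady state under frozen boundary values.  The
## scheme's fixed point is independent of the pseudo step, so after an
## initial settling stage the step is enlarged to flush the slow transients
## (recirculation bubbles, long-channel diffusion) cheaply.
runToSteady <- function(ops, bcs, config, dtPseudo = 0.01,
                        tol = 1e-11, maxIter = 1200, state = NULL) {
  mkCfg <- function(dt) new("SolverConfig", dt = dt, cycles = 2,
                            period = 2 * dt, linTol = config@linTol,
                            stepTol = config@stepTol,
                            advectionScheme = config@advectionScheme,
                            outputStride = 1, spinupCycles = 0)
  if (is.null(state)) state <- newFlowState(ops)
  frozen <- bcs(0)
  bcsF <- function(t) frozen
  stage <- list(list(dt = dtPseudo, iters = 150),
                list(dt = 10 * dtPseudo, iters = maxIter - 150))
  for (sg in stage) {
    cfg <- mkCfg(sg$dt)
    for (it in seq_len(sg$iters)) {
      prev <- state
      state <- stepFlow(state, 0, bcsF, cfg, ops)
      scale <- max(abs(state$u), abs(state$v), 1e-30)
      delta <- max(abs(state$u - prev$u), abs(state$v - prev$v)) / scale
      if (delta < tol) break
    }
    if (delta < tol) break
  }
  state
}

#' Steady flow solve
#'
#' Pseudo-time marches the transient scheme to a steady state under constant
#' inlet velocities; at convergence the splitting error vanishes and the
#' result is the steady Galerkin solution.
#'
#' @param mesh a \code{TriMesh}.
#' @param props a \code{FluidProps}.
#' @param vLad,vGraft constant cross-section-mean inlet velocities (m/s);
#'   \code{vLad} is ignored when the mesh has no LAD inlet.
#' @param tol relative step-increment convergence tolerance.
#' @param maxIter pseudo-time iteration cap.
#' @return list(ops =, state =) with the operator set and converged state.
#' @export
solveSteady <- function(mesh, props = fluidProps(), vLad = 0.02,
                        vGraft = 0.03, tol = 1e-7, maxIter = 800) {
  ops <- assembleOperators(mesh, props)
  if (!"GRAFT_INLET" %in% mesh@boundaryTag) {
    ## straight channel: only an LAD-style inlet
    geo <- inletGeometry(mesh, "LAD_INLET")
    wallNodes <- ops$dirNodes
    bcs <- function(t) {
      mag <- 6 * vLad * geo$zeta * (1 - geo$zeta)
      list(nodes = c(wallNodes, geo$nodes),
           ux = c(numeric(length(wallNodes)), mag * geo$dir[1]),
           uy = c(numeric(length(wallNodes)), mag * geo$dir[2]))
    }
  } else {
    hasLad <- "LAD_INLET" %in% mesh@boundaryTag
    cond <- new("ConditionSpec", name = "higher",
                stenosisDegree = if (hasLad) 0 else 1,
                ladWaveform = if (hasLad) makeWaveform(vLad, 0) else NULL,
                graftWaveform = makeWaveform(vGraft, 0))
    bcs <- conditionBC(ops, cond)
  }
  cfg <- solverConfig()
  state <- runToSteady(ops, bcs, cfg, tol = tol, maxIter = maxIter)
  list(ops = ops, state = state)
}

#' Run a pulsatile simulation for one condition
#'
#' Initializes with a steady solve at the phase-0 inlet values, runs
#' \code{spinupCycles} untracked preconditioning cycles, then
#' \code{config@cycles} counted cardiac cycles.  The final cycle's fields are
#' stored at the output stride; wall-sampled pressure and shear traces of the
#' last two counted cycles give the periodicity diagnostics (relative L2
#' difference over the cycle, the cyclic convergence measure).
#'
#' @param mesh a \code{TriMesh}.
#' @param condition a \code{ConditionSpec}; its waveforms must share
#'   \code{config@period}.
#' @param props a \code{FluidProps}.
#' @param config a \code{SolverConfig}.
#' @param verbose print per-cycle progress.
#' @return A \code{FlowSolution}.
#' @export
runSimulation <- function(mesh, condition, props = fluidProps(),
                          config = solverConfig(), verbose = FALSE) {
  stopifnot(is(condition, "ConditionSpec"))
  if (abs(condition@graftWaveform@period - config@period) > 1e-12)
    stop("condition waveforms must be defined on the solver period")
  ops <- assembleOperators(mesh, props)
  bcs <- conditionBC(ops, condition)
  nsteps <- round(config@period / config@dt)
  stride <- round(config@outputStride)
  nsamp <- nsteps %/% stride
  wallSel <- ops$bedge$tag == "WALL"
  nw <- sum(wallSel)

  state <- tryCatch(
    runToSteady(ops, bcs, config),
    error = function(e) stop(sprintf("initialisation failed: %s", conditionMessage(e))))
  tGlobal <- 0
  nSpin <- round(config@spinupCycles) * nsteps
  for (k in seq_len(nSpin)) {
    state <- stepFlow(state, tGlobal, bcs, config, ops)
    tGlobal <- tGlobal + config@dt
  }
  tGlobal <- 0  # waveforms are periodic; keep phase bookkeeping simple

  nc <- round(config@cycles)
  traceTau <- vector("list", 2); traceP <- vector("list", 2)
  snapU <- snapV <- snapP <- NULL
  divMax <- 0; fluxMax <- 0; graftPeak <- 0
  graftGeo <- inletGeometry(mesh, "GRAFT_INLET")
  fluxScale <- 1e-30
  for (cyc in seq_len(nc)) {
    last <- cyc == nc
    keepTrace <- cyc >= nc - 1
    if (keepTrace) {
      tT <- matrix(0, 2 * nw, nsamp)  # tauX rows then tauY rows
      tP <- matrix(0, nw, nsamp)
    }
    if (last) {
      snapU <- matrix(0, ops$n, nsamp + 1)
      snapV <- matrix(0, ops$n, nsamp + 1)
      snapP <- matrix(0, ops$n, nsamp + 1)
      snapU[, 1] <- state$u; snapV[, 1] <- state$v
      snapP[, 1] <- state$pOut %||% state$p
    }
    for (k in seq_len(nsteps)) {
      state <- stepFlow(state, tGlobal, bcs, config, ops)
      tGlobal <- tGlobal + config@dt
      divMax <- max(divMax, state$divResidual)
      fluxMax <- max(fluxMax, abs(state$fluxImbalance))
      gsp <- sqrt(state$u[graftGeo$nodes]^2 + state$v[graftGeo$nodes]^2)
      graftPeak <- max(graftPeak, gsp)
      influx <- abs(boundaryFlux(ops, state$u, state$v,
                                 ops$bedge$tag %in% c("LAD_INLET", "GRAFT_INLET")))
      fluxScale <- max(fluxScale, influx)
      if (k %% stride == 0) {
        ks <- k %/% stride
        if (keepTrace) {
          tw <- wallTraction(ops, state$u, state$v, wallSel)
          tT[, ks] <- c(tw$tx, tw$ty)
          e <- ops$bedge$e[wallSel, , drop = FALSE]
          pw <- state$pOut %||% state$p
          tP[, ks] <- (pw[e[, 1]] + pw[e[, 2]]) / 2
        }
        if (last) {
          snapU[, ks + 1] <- state$u; snapV[, ks + 1] <- state$v
          snapP[, ks + 1] <- state$pOut %||% state$p
        }
      }
    }
    if (keepTrace) {
      slot <- if (last) 2 else 1
      traceTau[[slot]] <- tT; traceP[[slot]] <- tP
    }
    if (verbose) message(sprintf("  cycle %d/%d done", cyc, nc))
  }
  perr <- list(
    pressure = normRel(traceP[[2]] - traceP[[1]], traceP[[1]]),
    wss = normRel(traceTau[[2]] - traceTau[[1]], traceTau[[1]]))
  new("FlowSolution", mesh = mesh,
      times = seq(0, config@period, length.out = nsamp + 1),
      u = snapU, v = snapV, p = snapP,
      wallTraces = list(tau = traceTau, p = traceP, wallSel = wallSel,
                        times = seq_len(nsamp) * stride * config@dt),
      periodicityError = perr,
      diagnostics = list(
        divergenceMax = divMax / fluxScale,
        fluxImbalanceMax = fluxMax, fluxScale = fluxScale,
        graftInletPeakSpeed = graftPeak,
        reynoldsMax = ops$rho * graftPeak * graftWidth(mesh) / ops$mu,
        condition = condition@name))
}

normRel <- function(d, ref) {
  r <- sqrt(sum(ref^2))
  if (r == 0) return(0)
  sqrt(sum(d^2)) / r
}

#' @export
setMethod("show", "FlowSolution", function(object) {
  cat(sprintf(
    "FlowSolution (%s): %d snapshots over %.3g s on %d nodes\n",
    object@diagnostics$condition %||% "?", length(object@times),
    max(object@times), nrow(object@u)))
  cat(sprintf("  periodicity error: pressure %.3g%%, wss %.3g%%\n",
              100 * object@periodicityError$pressure,
              100 * object@periodicityError$wss))
  cat(sprintf("  max |net boundary flux| %.3g m^2/s, graft inlet peak %.3g m/s\n",
              object@diagnostics$fluxImbalanceMax,
              object@diagnostics$graftInletPeakSpeed))
})
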