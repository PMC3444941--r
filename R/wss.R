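## Wall shear stress extraction and hemodynamic indices.
##
## The wall shear vector is the tangential part of the viscous traction
## mu (grad u + grad u^t) n, evaluated from the adjacent element's (constant)
## P1 velocity gradient and reported at boundary edge midpoints.  TAWSS is
## the cycle average of |tau|; OSI = 0.5 (1 - |int tau dt| / int |tau| dt),
## zero for unidirectional shear and 0.5 for zero-mean oscillatory shear.
## Both use trapezoidal quadrature on the stored time grid.

graftWidth <- function(mesh) {
  if (!is.null(mesh@meta$params)) mesh@meta$params@dGraft
  else mesh@meta$width %||% NA_real_
}

## Tangential viscous traction on selected boundary edges for one field.
wallTraction <- function(ops, u, v, sel) {
  bd <- ops$bedge
  idx <- which(sel)
  el <- bd$adjElem[idx]
  cl <- ops$cells[el, , drop = FALSE]
  b <- ops$b[el, , drop = FALSE]; cc <- ops$c[el, , drop = FALSE]
  dudx <- b[, 1] * u[cl[, 1]] + b[, 2] * u[cl[, 2]] + b[, 3] * u[cl[, 3]]
  dudy <- cc[, 1] * u[cl[, 1]] + cc[, 2] * u[cl[, 2]] + cc[, 3] * u[cl[, 3]]
  dvdx <- b[, 1] * v[cl[, 1]] + b[, 2] * v[cl[, 2]] + b[, 3] * v[cl[, 3]]
  dvdy <- cc[, 1] * v[cl[, 1]] + cc[, 2] * v[cl[, 2]] + cc[, 3] * v[cl[, 3]]
  nx <- bd$nx[idx]; ny <- bd$ny[idx]
  mu <- ops$mu
  tx <- mu * (2 * dudx * nx + (dudy + dvdx) * ny)
  ty <- mu * ((dudy + dvdx) * nx + 2 * dvdy * ny)
  tn <- tx * nx + ty * ny
  list(tx = tx - tn * nx, ty = ty - tn * ny)
}

## Order a region's boundary edges into chains and return cumulative
## arc-length coordinates of their midpoints.
.chainOrder <- function(mesh, idx) {
  e <- mesh@boundaryEdges[idx, , drop = FALSE]
  nodes <- mesh@nodes
  len <- sqrt((nodes[e[, 1], 1] - nodes[e[, 2], 1])^2 +
              (nodes[e[, 1], 2] - nodes[e[, 2], 2])^2)
  remaining <- seq_along(idx)
  order <- integer(0); sOut <- numeric(0); offset <- 0
  deg <- table(as.vector(e))
  while (length(remaining)) {
    ends <- names(deg[deg == 1])
    sub <- e[remaining, , drop = FALSE]
    startNode <- NA
    for (cand in as.integer(ends)) {
      if (cand %in% as.vector(sub)) { startNode <- cand; break }
    }
    if (is.na(startNode)) startNode <- sub[1, 1]   # closed loop fallback
    cur <- startNode; s <- 0
    repeat {
      hit <- remaining[which(e[remaining, 1] == cur | e[remaining, 2] == cur)]
      if (!length(hit)) break
      k <- hit[1]
      order <- c(order, k)
      sOut <- c(sOut, offset + s + len[k] / 2)
      s <- s + len[k]
      cur <- if (e[k, 1] == cur) e[k, 2] else e[k, 1]
      remaining <- setdiff(remaining, k)
    }
    offset <- offset + s
    deg <- table(as.vector(e[remaining, , drop = FALSE]))
  }
  list(order = order, s = sOut)
}

#' Extract the wall shear stress history along a wall region
#'
#' @param sol a \code{FlowSolution}.
#' @param region wall region tag (e.g. \code{"GRAFT_WALL"}).
#' @param props a \code{FluidProps} (must match the solve).
#' @return A \code{WallShearSeries} ordered by arc length, spanning one
#'   period.
#' @export
wallShearSeries <- function(sol, region, props = fluidProps(), ops = NULL) {
  mesh <- sol@mesh
  idx <- which(!is.na(mesh@wallRegion) & mesh@wallRegion == region)
  if (!length(idx)) stop(sprintf("missing region: %s", region))
  if (is.null(ops)) ops <- lightOperators(mesh, props)
  sel <- logical(nrow(mesh@boundaryEdges)); sel[idx] <- TRUE
  nt <- ncol(sol@u)
  ord <- .chainOrder(mesh, idx)
  np <- length(idx)
  tauX <- matrix(0, np, nt); tauY <- matrix(0, np, nt)
  for (j in seq_len(nt)) {
    tw <- wallTraction(ops, sol@u[, j], sol@v[, j], sel)
    tauX[, j] <- tw$tx[ord$order]
    tauY[, j] <- tw$ty[ord$order]
  }
  oIdx <- idx[ord$order]
  bd <- ops$bedge
  new("WallShearSeries", region = region, s = ord$s,
      points = cbind(bd$mx[oIdx], bd$my[oIdx]),
      normals = cbind(bd$nx[oIdx], bd$ny[oIdx]),
      times = sol@times, tauX = tauX, tauY = tauY)
}

#' Analytic wall shear series constructor
#'
#' Wraps caller-supplied shear vector histories (e.g. closed-form test
#' signals) in a \code{WallShearSeries} so they can be fed to
#' \code{\link{tawss}} and \code{\link{osi}}.
#'
#' @param times sample times spanning one period (s).
#' @param tauX,tauY matrices (points x times) or vectors (one point) of
#'   shear components (Pa).
#' @return A \code{WallShearSeries}.
#' @export
shearSeries <- function(times, tauX, tauY = NULL) {
  tauX <- rbind(tauX); if (is.null(tauY)) tauY <- 0 * tauX else tauY <- rbind(tauY)
  np <- nrow(tauX)
  new("WallShearSeries", region = "ANALYTIC", s = seq_len(np) - 1,
      points = matrix(0, np, 2), normals = matrix(rep(c(0, -1), each = np), np, 2),
      times = times, tauX = tauX, tauY = tauY)
}

.trapWeights <- function(times) {
  nt <- length(times)
  if (nt < 2) stop("incomplete period: need at least two samples")
  dt <- diff(times)
  if (any(dt <= 0)) stop("incomplete period: times must be increasing")
  w <- numeric(nt)
  w[1] <- dt[1] / 2; w[nt] <- dt[nt - 1] / 2
  if (nt > 2) w[2:(nt - 1)] <- (dt[-1] + dt[-(nt - 1)]) / 2
  w
}

#' Time-averaged wall shear stress
#'
#' Trapezoidal time integral of |tau| over the series' period, divided by the
#' period, per wall point.
#'
#' @param series a \code{WallShearSeries} spanning one full period.
#' @return TAWSS per wall point (Pa).
#' @export
tawss <- function(series) {
  w <- .trapWeights(series@times)
  T <- sum(w)
  mag <- sqrt(series@tauX^2 + series@tauY^2)
  as.vector(mag %*% w) / T
}

#' Oscillatory shear index
#'
#' OSI = 0.5 (1 - |int tau dt| / int |tau| dt) with trapezoidal quadrature of
#' both integrals; ranges from 0 (unidirectional shear) to 0.5 (zero-mean
#' oscillatory shear).  Points with identically zero shear get OSI = 0 (the
#' unidirectional limit).
#'
#' @param series a \code{WallShearSeries} spanning one full period.
#' @return OSI per wall point (dimensionless, in [0, 0.5]).
#' @export
osi <- function(series) {
  w <- .trapWeights(series@times)
  sx <- as.vector(series@tauX %*% w)
  sy <- as.vector(series@tauY %*% w)
  den <- as.vector(sqrt(series@tauX^2 + series@tauY^2) %*% w)
  out <- numeric(length(den))
  pos <- den > 0
  out[pos] <- 0.5 * (1 - sqrt(sx[pos]^2 + sy[pos]^2) / den[pos])
  pmin(pmax(out, 0), 0.5)
}

#' Reynolds number
#' @param v velocity scale (m/s).
#' @param d length scale (m).
#' @param props a \code{FluidProps}.
#' @return rho v d / mu.
#' @export
reynoldsNumber <- function(v, d, props = fluidProps()) {
  if (any(d <= 0)) stop("length scale must be positive")
  props@density * v * d / props@viscosity
}

#' Poiseuille reference wall shear (plane channel)
#' @param vMean cross-section mean velocity (m/s).
#' @param width channel width (m).
#' @param props a \code{FluidProps}.
#' @return tau0 = 6 mu vMean / width (Pa).
#' @export
poiseuilleReference <- function(vMean, width, props = fluidProps()) {
  if (any(width <= 0)) stop("width must be positive")
  6 * props@viscosity * vMean / width
}

#' Hemodynamic indices of a flow solution
#'
#' Computes per-wall-point TAWSS and OSI for every wall region of the mesh
#' plus length-weighted region summaries, the Poiseuille reference shear at
#' the graft mean flow, and the maximum instantaneous graft-inlet Reynolds
#' number.
#'
#' @param sol a \code{FlowSolution}.
#' @param condition the \code{ConditionSpec} that produced it.
#' @param props a \code{FluidProps}.
#' @return A \code{HemodynamicMetrics}.
#' @export
hemodynamicMetrics <- function(sol, condition, props = fluidProps()) {
  mesh <- sol@mesh
  ops <- lightOperators(mesh, props)
  regions <- sort(unique(mesh@wallRegion[!is.na(mesh@wallRegion)]))
  pw <- list(); sm <- list()
  for (rg in regions) {
    ser <- wallShearSeries(sol, rg, props, ops = ops)
    tw <- tawss(ser); os <- osi(ser)
    pw[[rg]] <- data.frame(region = rg, s = ser@s, tawss = tw, osi = os)
    idx <- which(!is.na(mesh@wallRegion) & mesh@wallRegion == rg)
    e <- mesh@boundaryEdges[idx, , drop = FALSE]
    len <- sqrt(rowSums((mesh@nodes[e[, 1], , drop = FALSE] -
                         mesh@nodes[e[, 2], , drop = FALSE])^2))
    lenOrd <- len[.chainOrder(mesh, idx)$order]
    sm[[rg]] <- data.frame(
      region = rg,
      meanTAWSS = sum(tw * lenOrd) / sum(lenOrd), maxTAWSS = max(tw),
      meanOSI = sum(os * lenOrd) / sum(lenOrd), maxOSI = max(os))
  }
  new("HemodynamicMetrics",
      pointwise = do.call(rbind, c(pw, list(make.row.names = FALSE))),
      summary = do.call(rbind, c(sm, list(make.row.names = FALSE))),
      tau0 = poiseuilleReference(condition@graftWaveform@meanVelocity,
                                 graftWidth(mesh), props),
      reynoldsMax = sol@diagnostics$reynoldsMax %||% NA_real_)
}

#' @export
setMethod("show", "HemodynamicMetrics", function(object) {
  cat("HemodynamicMetrics (tau0 =", signif(object@tau0, 4), "Pa, Re_max =",
      signif(object@reynoldsMax, 4), ")\n")
  print(object@summary, row.names = FALSE, digits = 4)
})
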