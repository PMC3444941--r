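## P1 finite-element operators for the incompressible flow solver.
##
## Discretization: linear (P1) triangles for both velocity and pressure,
## advanced by an incremental pressure-correction projection.  All constant
## operators (lumped mass, viscous stiffness, weak divergence, the projection
## matrix and its factorization, boundary bookkeeping) are assembled once per
## mesh; the convection + streamline-diffusion contribution is refreshed each
## step through a precomputed triplet-to-CSC aggregation map, so a time step
## costs one sparse LU (shared by both velocity components), one cached
## Cholesky solve, and a handful of sparse products.

## Boundary edge geometry: lengths, midpoints, adjacent elements and outward
## unit normals (oriented away from the opposite vertex of the adjacent
## triangle).
boundaryGeometry <- function(mesh) {
  nodes <- mesh@nodes; cells <- mesh@cells; be <- mesh@boundaryEdges
  n <- nrow(nodes); m <- nrow(cells)
  edgeKey <- function(a, bn) pmin(a, bn) * (n + 1) + pmax(a, bn)
  cellEdges <- rbind(cbind(cells[, 1], cells[, 2], cells[, 3]),
                     cbind(cells[, 2], cells[, 3], cells[, 1]),
                     cbind(cells[, 3], cells[, 1], cells[, 2]))
  ceKeys <- edgeKey(cellEdges[, 1], cellEdges[, 2])
  beKeys <- edgeKey(be[, 1], be[, 2])
  hit <- match(beKeys, ceKeys)
  if (anyNA(hit)) stop("boundary edge without adjacent cell")
  adjElem <- ((hit - 1L) %% m) + 1L
  opp <- cellEdges[hit, 3]
  ex <- nodes[be[, 2], 1] - nodes[be[, 1], 1]
  ey <- nodes[be[, 2], 2] - nodes[be[, 1], 2]
  elen <- sqrt(ex^2 + ey^2)
  nxv <- ey / elen; nyv <- -ex / elen
  mx <- (nodes[be[, 1], 1] + nodes[be[, 2], 1]) / 2
  my <- (nodes[be[, 1], 2] + nodes[be[, 2], 2]) / 2
  flipN <- (nodes[opp, 1] - mx) * nxv + (nodes[opp, 2] - my) * nyv > 0
  nxv[flipN] <- -nxv[flipN]; nyv[flipN] <- -nyv[flipN]
  list(e = be, tag = mesh@boundaryTag, region = mesh@wallRegion,
       len = elen, nx = nxv, ny = nyv, adjElem = adjElem, mx = mx, my = my)
}

## Minimal operator set for wall-shear post-processing (no linear algebra).
lightOperators <- function(mesh, props) {
  nodes <- mesh@nodes; cells <- mesh@cells
  x1 <- nodes[cells[, 1], 1]; y1 <- nodes[cells[, 1], 2]
  x2 <- nodes[cells[, 2], 1]; y2 <- nodes[cells[, 2], 2]
  x3 <- nodes[cells[, 3], 1]; y3 <- nodes[cells[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  list(cells = cells,
       b = cbind(y2 - y3, y3 - y1, y1 - y2) / det,
       c = cbind(x3 - x2, x1 - x3, x2 - x1) / det,
       mu = props@viscosity, bedge = boundaryGeometry(mesh))
}

#' Assemble the discrete operator set for a mesh
#'
#' Builds the sparse P1 operators: lumped mass, viscous stiffness (symmetric
#' positive semidefinite), weak divergence/gradient pair (the discrete
#' gradient is the negative transpose of the divergence up to boundary
#' terms), the exact-projection pressure matrix with its Cholesky
#' factorization, and boundary condition bookkeeping.
#'
#' @param mesh a \code{TriMesh}.
#' @param props a \code{FluidProps}.
#' @return An opaque operator set (class \code{"flowOperators"}).
#' @export
assembleOperators <- function(mesh, props) {
  stopifnot(is(mesh, "TriMesh"), is(props, "FluidProps"))
  nodes <- mesh@nodes; cells <- mesh@cells
  n <- nrow(nodes); m <- nrow(cells)
  x1 <- nodes[cells[, 1], 1]; y1 <- nodes[cells[, 1], 2]
  x2 <- nodes[cells[, 2], 1]; y2 <- nodes[cells[, 2], 2]
  x3 <- nodes[cells[, 3], 1]; y3 <- nodes[cells[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  if (any(det <= 0)) stop("singular assembly: degenerate or inverted triangle")
  area <- det / 2
  ## shape function gradients: phi_i = (a_i + b_i x + c_i y)
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / det

  ## triplet layout: for jj in 1:3, for ii in 1:3 (column-major in (ii, jj))
  tripI <- as.vector(cells[, rep(1:3, times = 3)])
  tripJ <- as.vector(cells[, rep(1:3, each = 3)])
  pairIdx <- cbind(rep(1:3, times = 3), rep(1:3, each = 3))

  ## viscous stiffness mu * grad phi_i . grad phi_j
  mu <- props@viscosity; rho <- props@density
  Kvals <- matrix(0, m, 9)
  for (q in 1:9) {
    ii <- pairIdx[q, 1]; jj <- pairIdx[q, 2]
    Kvals[, q] <- mu * area * (b[, ii] * b[, jj] + cc[, ii] * cc[, jj])
  }
  K <- sparseMatrix(i = tripI, j = tripJ, x = as.vector(Kvals), dims = c(n, n))

  ## weak divergence: (D u)_q = int phi_q du/dx (+ dv/dy via Dy)
  DxVals <- matrix(0, m, 9); DyVals <- matrix(0, m, 9)
  for (q in 1:9) {
    jj <- pairIdx[q, 2]
    DxVals[, q] <- area / 3 * b[, jj]
    DyVals[, q] <- area / 3 * cc[, jj]
  }
  Dx <- sparseMatrix(i = tripI, j = tripJ, x = as.vector(DxVals), dims = c(n, n))
  Dy <- sparseMatrix(i = tripI, j = tripJ, x = as.vector(DyVals), dims = c(n, n))

  ## lumped (geometric) mass
  MLgeo <- as.vector(sparseMatrix(i = tripI, j = rep(1L, length(tripI)),
                                  x = rep(area / 9, 9), dims = c(n, 1)))
  ## note: each element contributes area/3 per node over the 9 triplets
  ## (3 occurrences of each node) -> area/9 per triplet occurrence

  ## momentum matrix template: pattern of K (covers convection + mass diag)
  Atmpl <- K
  Atmpl@x <- Atmpl@x + 0                 # private copy
  keyOf <- function(i, j) as.numeric(i) + (as.numeric(j) - 1) * n
  colIdx <- rep(seq_len(n), diff(Atmpl@p))
  patKeys <- keyOf(Atmpl@i + 1L, colIdx)
  tripKeys <- keyOf(tripI, tripJ)
  map <- match(tripKeys, patKeys)
  Agg <- sparseMatrix(i = map, j = seq_along(map), x = 1,
                      dims = c(length(Atmpl@x), length(map)))
  ## constant part of A (stiffness) in template order; mass added per dt later
  constX <- Atmpl@x
  diagPos <- match(keyOf(seq_len(n), seq_len(n)), patKeys)

  ## boundary bookkeeping
  tag <- mesh@boundaryTag
  be <- mesh@boundaryEdges
  dirNodes <- sort(unique(as.vector(be[tag %in%
    c("WALL", "LAD_INLET", "GRAFT_INLET"), ])))
  freeU <- setdiff(seq_len(n), dirNodes)
  outletNodes <- setdiff(unique(as.vector(be[tag == "OUTLET", ])), dirNodes)

  bd <- boundaryGeometry(mesh)
  elen <- bd$len; nxv <- bd$nx; nyv <- bd$ny

  ## exact projection matrix B = D_f MLgeo_f^{-1} D_f^T (both components),
  ## with pressure enforced at all nodes except the outlet (phi = 0 there)
  Dxf <- Dx[, freeU, drop = FALSE]; Dyf <- Dy[, freeU, drop = FALSE]
  Minv <- Diagonal(x = 1 / MLgeo[freeU])
  B <- Dxf %*% Minv %*% Matrix::t(Dxf) + Dyf %*% Minv %*% Matrix::t(Dyf)
  pFree <- setdiff(seq_len(n), outletNodes)
  dB <- Matrix::diag(B)
  locked <- pFree[dB[pFree] < 1e-8 * stats::median(dB)]
  if (length(locked)) pFree <- setdiff(pFree, locked)
  Bff <- Matrix::forceSymmetric(B[pFree, pFree, drop = FALSE])
  ## B admits an exact checkerboard null vector on structured triangulations;
  ## a tiny diagonal shift makes the factorization robust, and the null
  ## component it suppresses has no effect on the corrected velocity
  Bchol <- Matrix::Cholesky(Bff, LDL = FALSE, perm = TRUE,
                            Imult = 1e-10 * stats::median(dB))
  ## smooth pressure-Poisson operator (P1 Laplacian): spectrally close to B
  ## but free of the equal-order checkerboard modes; used for the pressure
  ## update, while B does an exact divergence cleanup on the velocity only
  Kp <- K / mu
  Lff <- Matrix::forceSymmetric(Kp[pFree, pFree, drop = FALSE])
  Lchol <- Matrix::Cholesky(Lff, LDL = FALSE, perm = TRUE)

  ## interior pressure nodes (patch not touching the boundary) for the
  ## divergence diagnostic
  bdNodes <- unique(as.vector(be))
  touching <- unique(as.vector(cells[rowSums(matrix(cells %in% bdNodes, m, 3)) > 0, ]))
  divCheckNodes <- setdiff(pFree, touching)

  ops <- list(
    mesh = mesh, props = props, n = n, m = m, cells = cells,
    area = area, b = b, c = cc, hElem = sqrt(2 * area),
    mu = mu, rho = rho,
    K = K, Dx = Dx, Dy = Dy, MLgeo = MLgeo,
    Atmpl = Atmpl, Agg = Agg, constX = constX, diagPos = diagPos,
    tripI = tripI, tripJ = tripJ, pairIdx = pairIdx,
    dirNodes = dirNodes, freeU = freeU, outletNodes = outletNodes,
    pFree = pFree, Bchol = Bchol, Lchol = Lchol,
    divCheckNodes = divCheckNodes,
    bedge = bd
  )
  ## free-submatrix extraction map: positions of A[free,free] entries in A@x
  Asub <- Atmpl[freeU, freeU, drop = FALSE]
  nf <- length(freeU)
  subColIdx <- rep(seq_len(nf), diff(Asub@p))
  subKeys <- keyOf(freeU[Asub@i + 1L], freeU[subColIdx])
  ops$mapFF <- match(subKeys, patKeys)
  ops$AffTmpl <- Asub
  ## unit outlet-correction flux (for the global mass closure)
  ops$outletUnitFlux <- {
    sel <- tag == "OUTLET"
    s <- 0
    if (any(sel)) {
      w1 <- be[sel, 1] %in% outletNodes
      w2 <- be[sel, 2] %in% outletNodes
      s <- sum(elen[sel] * (w1 + w2) / 2 * nxv[sel])  # unit u along +x
    }
    s
  }
  class(ops) <- "flowOperators"
  ops
}

#' @export
print.flowOperators <- function(x, ...) {
  cat("flowOperators:", x$n, "nodes,", x$m, "elements,",
      length(x$freeU), "free velocity nodes,",
      length(x$pFree), "pressure constraints\n")
  invisible(x)
}

## Boundary flux integral of a velocity field (outward positive).
boundaryFlux <- function(ops, u, v, sel = NULL) {
  bd <- ops$bedge
  idx <- if (is.null(sel)) seq_along(bd$len) else which(sel)
  e <- bd$e[idx, , drop = FALSE]
  un <- ((u[e[, 1]] + u[e[, 2]]) / 2) * bd$nx[idx] +
        ((v[e[, 1]] + v[e[, 2]]) / 2) * bd$ny[idx]
  sum(un * bd$len[idx])
}

## Convection (+ optional streamline diffusion) triplet values for a
## convecting field (wx, wy); returns the momentum matrix x-slot.
momentumMatrixX <- function(ops, wx, wy, dt, supg = TRUE) {
  cells <- ops$cells; area <- ops$area
  wbx <- (wx[cells[, 1]] + wx[cells[, 2]] + wx[cells[, 3]]) / 3
  wby <- (wy[cells[, 1]] + wy[cells[, 2]] + wy[cells[, 3]]) / 3
  V <- matrix(0, ops$m, 3)
  for (k in 1:3) V[, k] <- area / 3 * (wbx * ops$b[, k] + wby * ops$c[, k])
  trip <- matrix(0, ops$m, 9)
  rho <- ops$rho
  for (q in 1:9) trip[, q] <- rho * V[, ops$pairIdx[q, 2]]
  if (supg) {
    speed <- sqrt(wbx^2 + wby^2)
    nu <- ops$mu / rho
    pe <- speed * ops$hElem / (2 * nu)
    tau <- ifelse(speed > 1e-12,
                  ops$hElem / (2 * speed) * pmin(1, pe / 3), 0)
    fac <- ifelse(area > 0, 9 * rho * tau / area, 0)
    for (q in 1:9) {
      ii <- ops$pairIdx[q, 1]; jj <- ops$pairIdx[q, 2]
      trip[, q] <- trip[, q] + fac * V[, ii] * V[, jj]
    }
  }
  xv <- ops$constX + as.vector(ops$Agg %*% as.vector(trip))
  xv[ops$diagPos] <- xv[ops$diagPos] + ops$rho * ops$MLgeo / dt
  xv
}
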