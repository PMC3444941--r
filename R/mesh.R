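## --- small mesh utilities -------------------------------------------------

## Signed triangle areas (positive = counterclockwise).
triangleAreas <- function(nodes, cells) {
  x1 <- nodes[cells[, 1], 1]; y1 <- nodes[cells[, 1], 2]
  x2 <- nodes[cells[, 2], 1]; y2 <- nodes[cells[, 2], 2]
  x3 <- nodes[cells[, 3], 1]; y3 <- nodes[cells[, 3], 2]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' Per-triangle mesh quality
#'
#' Quality is the classic ratio 2 r_in / R_circ (1 for equilateral, 0 for
#' degenerate triangles).
#'
#' @param mesh a \code{TriMesh}.
#' @return Numeric vector of per-cell qualities.
#' @export
meshQuality <- function(mesh) {
  nodes <- mesh@nodes; cells <- mesh@cells
  p1 <- nodes[cells[, 1], , drop = FALSE]
  p2 <- nodes[cells[, 2], , drop = FALSE]
  p3 <- nodes[cells[, 3], , drop = FALSE]
  a <- sqrt(rowSums((p2 - p3)^2))
  b <- sqrt(rowSums((p1 - p3)^2))
  cc <- sqrt(rowSums((p1 - p2)^2))
  area <- abs(triangleAreas(nodes, cells))
  s <- (a + b + cc) / 2
  rin <- area / s
  rcirc <- a * b * cc / (4 * area)
  2 * rin / rcirc
}

#' Total mesh area
#' @param mesh a \code{TriMesh}.
#' @return Sum of triangle areas (m^2).
#' @export
meshArea <- function(mesh) sum(triangleAreas(mesh@nodes, mesh@cells))

## Two-sided tanh-stretched distribution of [0,1] into n cells whose first
## (and last) interval is approximately endFrac of the span.
twoSidedStretch <- function(n, endFrac) {
  if (n < 2 || endFrac >= 1 / n) return(seq(0, 1, length.out = n + 1))
  endFrac <- max(endFrac, 0.2 / n^2 + 1e-4)
  f <- function(beta) {
    0.5 * (tanh(beta * (2 / n - 1)) + tanh(beta)) / tanh(beta) - endFrac
  }
  beta <- stats::uniroot(f, c(1e-4, 25))$root
  xi <- seq(0, 1, length.out = n + 1)
  eta <- 0.5 * (1 + tanh(beta * (2 * xi - 1)) / tanh(beta))
  eta[1] <- 0; eta[n + 1] <- 1
  eta
}

## Station sequence on [x0, x1] following a local spacing function s(x),
## hitting both endpoints exactly.
gradedStations <- function(x0, x1, spacingFun, nMin = 4) {
  xs <- seq(x0, x1, length.out = 2001)
  dens <- 1 / spacingFun(xs)
  cum <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(xs)))
  n <- max(nMin, ceiling(cum[length(cum)]))
  targets <- seq(0, cum[length(cum)], length.out = n + 1)
  out <- stats::approx(cum, xs, targets, ties = "ordered")$y
  out[1] <- x0; out[n + 1] <- x1
  out
}

## --- bypass mesh ----------------------------------------------------------

#' Generate a tagged triangle mesh of the bypass domain
#'
#' Meshes the outline from \code{\link{buildGeometry}} with mapped structured
#' blocks (LAD channel and graft channel, conforming along the anastomosis
#' opening) split into triangles in alternating (union-jack) orientation.
#' Node spacing is graded toward all walls so that the first off-wall layer is
#' no thicker than \code{targetH / refineWall}; the streamwise spacing narrows
#' with the stenosed channel width to bound the cell aspect ratio.
#'
#' For meshing purposes the throat width is clamped from below at 15% of the
#' LAD width; with the canonical stenosis degrees the clamp is only active at
#' full occlusion, where the proximal inlet is walled off and the stump is
#' stagnant.
#'
#' @param outline a \code{graftOutline} from \code{\link{buildGeometry}}.
#' @param targetH target element size (m).
#' @param refineWall near-wall refinement factor (>= 1).
#' @param qualityFloor minimum admissible cell quality (see
#'   \code{\link{meshQuality}}).
#' @param wFloor meshed-throat width floor as a fraction of the LAD width.
#' @return A \code{TriMesh}.
#' @export
generateMesh <- function(outline, targetH = 6e-4, refineWall = 4,
                         qualityFloor = 0.01, wFloor = 0.15) {
  if (!inherits(outline, "graftOutline"))
    stop("outline must come from buildGeometry()")
  p <- outline$params
  J <- outline$junction
  if (targetH <= 0 || refineWall < 1) stop("invalid meshing parameters")
  yc <- p@dLad / 2
  wMesh <- function(x) pmax(wFloor * p@dLad, stenosisProfile(x, p))

  ## streamwise stations: proximal (graded with the constriction), opening
  ## (graded toward heel and toe), distal (uniform)
  xProx <- gradedStations(0, J$xh, function(x)
    targetH * pmax(0.45, wMesh(x) / p@dLad))
  nOpen <- max(8, round(J$opening / targetH))
  feOpen <- (targetH / (refineWall * sin(J$theta))) / J$opening
  xOpen <- J$xh + J$opening * twoSidedStretch(nOpen, feOpen)
  nDist <- max(4, ceiling(p@lDist / targetH))
  xDist <- seq(J$xt, J$xTotal, length.out = nDist + 1)
  xs <- c(xProx, xOpen[-1], xDist[-1])
  iHeel <- length(xProx)
  iToe <- iHeel + nOpen
  nx <- length(xs)

  ## cross-channel levels, graded toward both walls
  ny <- max(8, round(p@dLad / targetH))
  etaY <- twoSidedStretch(ny, (targetH / refineWall) / p@dLad)
  nyp <- ny + 1

  idL <- function(i, j) (i - 1L) * nyp + j
  wAll <- wMesh(xs)
  nodesL <- cbind(rep(xs, each = nyp),
                  rep(yc, nx * nyp) + rep(wAll, each = nyp) * (etaY - 0.5))

  ## graft block: cross index follows the opening stations, along index runs
  ## from the inlet (l = 1) to the junction row (l = nL + 1, shared nodes)
  xi <- (xOpen - J$xh) / J$opening
  nK <- length(xi)
  nL <- max(6, round(p@lGraft / targetH))
  etaG <- seq(0, 1, length.out = nL + 1)
  inletPts <- cbind(J$P1[1] + xi * (J$P2[1] - J$P1[1]),
                    J$P1[2] + xi * (J$P2[2] - J$P1[2]))
  juncPts <- cbind(J$A[1] + xi * (J$B[1] - J$A[1]),
                   J$A[2] + xi * (J$B[2] - J$A[2]))
  NL <- nx * nyp
  idG <- function(k, l) {
    ifelse(l == nL + 1L, idL(iHeel + k - 1L, nyp), NL + (k - 1L) * nL + l)
  }
  nodesG <- matrix(0, nK * nL, 2)
  for (k in seq_len(nK)) {
    e <- etaG[seq_len(nL)]
    nodesG[(k - 1L) * nL + seq_len(nL), ] <-
      cbind((1 - e) * inletPts[k, 1] + e * juncPts[k, 1],
            (1 - e) * inletPts[k, 2] + e * juncPts[k, 2])
  }
  nodes <- rbind(nodesL, nodesG)

  ## triangles, union-jack split
  quadTris <- function(n00, n10, n11, n01, parity) {
    even <- parity %% 2L == 0L
    rbind(
      cbind(n00[even], n10[even], n11[even]),
      cbind(n00[even], n11[even], n01[even]),
      cbind(n00[!even], n10[!even], n01[!even]),
      cbind(n10[!even], n11[!even], n01[!even])
    )
  }
  ij <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny))
  cellsL <- quadTris(idL(ij$i, ij$j), idL(ij$i + 1L, ij$j),
                     idL(ij$i + 1L, ij$j + 1L), idL(ij$i, ij$j + 1L),
                     ij$i + ij$j)
  kl <- expand.grid(k = seq_len(nK - 1L), l = seq_len(nL))
  cellsG <- quadTris(idG(kl$k, kl$l), idG(kl$k + 1L, kl$l),
                     idG(kl$k + 1L, kl$l + 1L), idG(kl$k, kl$l + 1L),
                     kl$k + kl$l)
  cells <- rbind(cellsL, cellsG)
  storage.mode(cells) <- "integer"
  ## enforce positive orientation
  a <- triangleAreas(nodes, cells)
  flip <- a < 0
  if (any(flip)) cells[flip, c(2, 3)] <- cells[flip, c(3, 2)]

  ## boundary edges with tags
  edges <- list(); tags <- character(); regions <- character()
  addEdges <- function(n1, n2, tag, region = NA_character_) {
    edges[[length(edges) + 1L]] <<- cbind(n1, n2)
    tags <<- c(tags, rep(tag, length(n1)))
    if (length(region) == 1L) region <- rep(region, length(n1))
    stopifnot(length(region) == length(n1))
    regions <<- c(regions, region)
  }
  anastWin <- c(J$xh - p@dGraft, J$xt + p@dGraft)
  ladRegion <- function(xmid) {
    ifelse(xmid >= anastWin[1] & xmid <= anastWin[2], "ANASTOMOSIS",
           ifelse(xmid < anastWin[1], "LAD_WALL_PROX", "LAD_WALL_DIST"))
  }
  js <- seq_len(ny)
  inletTag <- if (p@stenosisDegree >= 1) "WALL" else "LAD_INLET"
  addEdges(idL(1L, js + 1L), idL(1L, js), inletTag,
           if (p@stenosisDegree >= 1) "LAD_WALL_PROX" else NA_character_)
  addEdges(idL(nx, js), idL(nx, js + 1L), "OUTLET")
  is <- seq_len(nx - 1L)
  xmid <- (xs[-1] + xs[-nx]) / 2
  addEdges(idL(is, 1L), idL(is + 1L, 1L), "WALL", ladRegion(xmid))
  topIs <- is[!(is >= iHeel & is < iToe)]          # skip the opening
  addEdges(idL(topIs + 1L, nyp), idL(topIs, nyp), "WALL", ladRegion(xmid[topIs]))
  ls <- seq_len(nL)
  heelIds1 <- idG(rep(1L, nL), ls); heelIds2 <- idG(rep(1L, nL), ls + 1L)
  toeIds1 <- idG(rep(nK, nL), ls); toeIds2 <- idG(rep(nK, nL), ls + 1L)
  distHeel <- sqrt(rowSums((cbind(
    (nodes[heelIds1, 1] + nodes[heelIds2, 1]) / 2 - J$A[1],
    (nodes[heelIds1, 2] + nodes[heelIds2, 2]) / 2 - J$A[2]))^2))
  distToe <- sqrt(rowSums((cbind(
    (nodes[toeIds1, 1] + nodes[toeIds2, 1]) / 2 - J$B[1],
    (nodes[toeIds1, 2] + nodes[toeIds2, 2]) / 2 - J$B[2]))^2))
  addEdges(heelIds2, heelIds1, "WALL",
           ifelse(distHeel < p@dGraft, "ANASTOMOSIS", "GRAFT_WALL"))
  addEdges(toeIds1, toeIds2, "WALL",
           ifelse(distToe < p@dGraft, "ANASTOMOSIS", "GRAFT_WALL"))
  ks <- seq_len(nK - 1L)
  addEdges(idG(ks + 1L, rep(1L, nK - 1L)), idG(ks, rep(1L, nK - 1L)),
           "GRAFT_INLET")
  boundaryEdges <- do.call(rbind, edges)
  storage.mode(boundaryEdges) <- "integer"

  mesh <- new("TriMesh", nodes = nodes, cells = cells,
              boundaryEdges = boundaryEdges, boundaryTag = tags,
              wallRegion = regions,
              meta = list(params = p, junction = J, targetH = targetH,
                          refineWall = refineWall, kind = "bypass"))
  validObject(mesh)
  q <- min(meshQuality(mesh))
  if (q < qualityFloor)
    stop(sprintf("meshing failure: min cell quality %.4g below floor %.4g",
                 q, qualityFloor))
  mesh
}

## --- straight channel mesh (validation oracles) ---------------------------

#' Mesh a straight 2D channel
#'
#' Rectangular channel of the given width and length, used by the Poiseuille
#' and Womersley validation oracles.  Walls are tagged \code{WALL} with region
#' \code{CHANNEL_WALL}; the open ends are \code{LAD_INLET} (x = 0) and
#' \code{OUTLET}.
#'
#' @param width,length channel dimensions (m).
#' @param targetH target element size (m).
#' @param refineWall near-wall refinement factor.
#' @return A \code{TriMesh}.
#' @export
channelMesh <- function(width, length, targetH = 3e-4, refineWall = 6) {
  nx <- max(4, ceiling(length / targetH))
  ny <- max(8, round(width / targetH))
  xs <- seq(0, length, length.out = nx + 1)
  etaY <- twoSidedStretch(ny, (targetH / refineWall) / width)
  nyp <- ny + 1
  idL <- function(i, j) (i - 1L) * nyp + j
  nodes <- cbind(rep(xs, each = nyp), rep(width * etaY, nx + 1))
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  even <- (ij$i + ij$j) %% 2L == 0L
  n00 <- idL(ij$i, ij$j); n10 <- idL(ij$i + 1L, ij$j)
  n11 <- idL(ij$i + 1L, ij$j + 1L); n01 <- idL(ij$i, ij$j + 1L)
  cells <- rbind(
    cbind(n00[even], n10[even], n11[even]),
    cbind(n00[even], n11[even], n01[even]),
    cbind(n00[!even], n10[!even], n01[!even]),
    cbind(n10[!even], n11[!even], n01[!even])
  )
  storage.mode(cells) <- "integer"
  a <- triangleAreas(nodes, cells)
  flip <- a < 0
  if (any(flip)) cells[flip, c(2, 3)] <- cells[flip, c(3, 2)]
  js <- seq_len(ny); is <- seq_len(nx)
  edges <- rbind(
    cbind(idL(1L, js + 1L), idL(1L, js)),
    cbind(idL(nx + 1L, js), idL(nx + 1L, js + 1L)),
    cbind(idL(is, 1L), idL(is + 1L, 1L)),
    cbind(idL(is + 1L, nyp), idL(is, nyp))
  )
  storage.mode(edges) <- "integer"
  tags <- c(rep("LAD_INLET", ny), rep("OUTLET", ny), rep("WALL", 2 * nx))
  regions <- c(rep(NA_character_, 2 * ny), rep("CHANNEL_WALL", 2 * nx))
  mesh <- new("TriMesh", nodes = nodes, cells = cells, boundaryEdges = edges,
              boundaryTag = tags, wallRegion = regions,
              meta = list(kind = "channel", width = width, length = length,
                          targetH = targetH, refineWall = refineWall))
  validObject(mesh)
  mesh
}

#' @export
setMethod("show", "TriMesh", function(object) {
  cat("TriMesh:", nrow(object@nodes), "nodes,", nrow(object@cells),
      "triangles,", nrow(object@boundaryEdges), "boundary edges\n")
  cat("  tags:", paste(sprintf("%s(%d)", names(table(object@boundaryTag)),
                               table(object@boundaryTag)), collapse = " "), "\n")
  wr <- table(object@wallRegion[!is.na(object@wallRegion)])
  if (length(wr))
    cat("  wall regions:", paste(sprintf("%s(%d)", names(wr), wr),
                                 collapse = " "), "\n")
  cat(sprintf("  area %.4g m^2, min quality %.3f\n",
              meshArea(object), min(meshQuality(object))))
})
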