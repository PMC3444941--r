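#' Create geometry parameters for the planar bypass model
#'
#' Defaults follow the idealized ITA-LAD bypass: LAD width 4.5 mm, graft width
#' 4.6 mm, 45 degree anastomosis.  Segment lengths default to ten LAD widths
#' of proximal and distal LAD and eight graft widths of graft so that inlet
#' profiles develop before reaching the junction; the stenosis bump is two LAD
#' widths long and centered in the proximal segment.
#'
#' @param dLad,dGraft channel widths (m).
#' @param angle anastomosis angle (degrees, strictly between 0 and 90).
#' @param stenosisDegree fractional diameter reduction in [0, 1].
#' @param lProx,lDist,lGraft segment lengths (m).
#' @param lSten stenosis bump length (m).
#' @param xSten bump center position along the proximal LAD (m).
#' @return A validated \code{GeometryParams} object.
#' @export
geometryParams <- function(dLad = 4.5e-3, dGraft = 4.6e-3, angle = 45,
                           stenosisDegree = 0,
                           lProx = 10 * dLad, lDist = 10 * dLad,
                           lGraft = 8 * dGraft, lSten = 2 * dLad,
                           xSten = lProx / 2) {
  new("GeometryParams", dLad = dLad, dGraft = dGraft, angle = angle,
      stenosisDegree = stenosisDegree, lProx = lProx, lDist = lDist,
      lGraft = lGraft, lSten = lSten, xSten = xSten)
}

#' Local LAD channel width under the stenosis profile
#'
#' Outside the bump the width equals \code{dLad}; inside, a smooth symmetric
#' raised-cosine constriction reduces the width to
#' \code{dLad * (1 - stenosisDegree)} at the bump center.  The profile is C1
#' at the bump boundaries and symmetric about \code{xSten}.
#'
#' @param x positions along the LAD axis (m); vectorized.
#' @param p a \code{GeometryParams} object.
#' @return Channel widths (m), same length as \code{x}.
#' @export
stenosisProfile <- function(x, p) {
  stopifnot(is(p, "GeometryParams"))
  validObject(p)
  w <- rep(p@dLad, length(x))
  xi <- (x - p@xSten) / p@lSten
  inside <- abs(xi) <= 0.5
  ## cos^2 taper: value (1 - degree) at center, 1 at bump edges, C1 there
  w[inside] <- p@dLad * (1 - p@stenosisDegree * cos(pi * xi[inside])^2)
  w
}

## Junction layout shared by the outline builder and the mesher.
## LAD axis = +x, centerline y = dLad/2, walls at dLad/2 +/- width(x)/2.
## Graft attaches to the top wall (y = dLad) between heel A and toe B; its
## axis points along (cos theta, -sin theta) (downstream merge).
junctionLayout <- function(p) {
  theta <- p@angle * pi / 180
  opening <- p@dGraft / sin(theta)
  xh <- p@lProx
  xt <- xh + opening
  A <- c(xh, p@dLad)                     # heel
  B <- c(xt, p@dLad)                     # toe
  axis <- c(cos(theta), -sin(theta))     # graft flow direction
  tHeel <- p@lGraft                      # heel-side wall length
  tToe <- p@lGraft + p@dGraft / tan(theta)
  P1 <- A - tHeel * axis                 # inlet corner on heel-side wall
  P2 <- B - tToe * axis                  # inlet corner on toe-side wall
  list(theta = theta, opening = opening, xh = xh, xt = xt, A = A, B = B,
       axis = axis, tHeel = tHeel, tToe = tToe, P1 = P1, P2 = P2,
       xTotal = xt + p@lDist)
}

#' Build the tagged planar outline of the bypass domain
#'
#' Returns the closed, counterclockwise outline of the 2D domain: proximal LAD
#' with the stenosis profile applied, distal LAD, and the graft channel
#' meeting the LAD top wall at the anastomosis angle with sharp heel and toe.
#' Open ends are tagged \code{LAD_INLET} (absent for full occlusion, where the
#' proximal cap is a wall), \code{GRAFT_INLET} and \code{OUTLET}.
#'
#' @param p a \code{GeometryParams} object.
#' @param nWall number of sample points per wall polyline segment.
#' @return A list of class \code{"graftOutline"}: segments (each with a point
#'   matrix and a tag), the geometry parameters, and the junction layout.
#' @export
buildGeometry <- function(p, nWall = 200) {
  stopifnot(is(p, "GeometryParams"))
  validObject(p)
  J <- junctionLayout(p)
  if (J$opening > 50 * p@dGraft)
    stop("geometry failure: anastomosis angle too shallow, graft opening degenerates")
  if (p@xSten + p@lSten / 2 > J$xh)
    stop("geometry failure: stenosis bump overlaps the anastomosis junction")
  yc <- p@dLad / 2
  xProx <- seq(0, J$xh, length.out = nWall)
  xDist <- seq(J$xt, J$xTotal, length.out = nWall)
  wProx <- stenosisProfile(xProx, p)
  yBotAll <- function(x) yc - stenosisProfile(x, p) / 2
  seg <- list()
  add <- function(pts, tag) seg[[length(seg) + 1L]] <<- list(points = pts, tag = tag)
  xAll <- c(xProx, xDist)
  ## bottom wall, left to right (domain on the left of each directed segment
  ## when traversing counterclockwise)
  add(cbind(xAll, yBotAll(xAll)), "WALL")
  ## outlet, bottom to top
  add(rbind(c(J$xTotal, yc - p@dLad / 2), c(J$xTotal, yc + p@dLad / 2)), "OUTLET")
  ## distal top wall, right to toe
  add(cbind(rev(xDist), yc + p@dLad / 2), "WALL")
  ## toe-side graft wall, toe up to inlet corner
  add(rbind(J$B, J$P2), "WALL")
  ## graft inlet, toe corner to heel corner
  add(rbind(J$P2, J$P1), "GRAFT_INLET")
  ## heel-side graft wall, inlet corner down to heel
  add(rbind(J$P1, J$A), "WALL")
  ## proximal top wall, heel back to LAD inlet
  add(cbind(rev(xProx), yc + rev(wProx) / 2), "WALL")
  ## LAD inlet, top to bottom; a wall cap for full occlusion
  inletTag <- if (p@stenosisDegree >= 1) "WALL" else "LAD_INLET"
  add(rbind(c(0, yc + p@dLad / 2), c(0, yc - p@dLad / 2)), inletTag)
  structure(list(segments = seg, params = p, junction = J),
            class = "graftOutline")
}

#' @export
print.graftOutline <- function(x, ...) {
  tags <- vapply(x$segments, `[[`, "", "tag")
  cat("graftOutline:", length(x$segments), "segments; open ends:",
      paste(setdiff(unique(tags), "WALL"), collapse = ", "), "\n")
  cat(sprintf("  stenosis degree %.2f, junction opening %.3f mm\n",
              x$params@stenosisDegree, 1e3 * x$junction$opening))
  invisible(x)
}

## Polygon vertices of the outline (closed, counterclockwise, deduplicated).
outlinePolygon <- function(outline) {
  pts <- do.call(rbind, lapply(outline$segments, `[[`, "points"))
  keep <- c(TRUE, rowSums(abs(diff(pts)))/2 > 1e-14)
  pts <- pts[keep, , drop = FALSE]
  if (sum(abs(pts[1, ] - pts[nrow(pts), ])) < 1e-14)
    pts <- pts[-nrow(pts), , drop = FALSE]
  pts
}

## Shoelace area of a closed polygon (positive if counterclockwise).
polygonArea <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}
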