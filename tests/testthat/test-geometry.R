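test_that("stenosis profile reproduces the diameter-reduction definition", {
  p0 <- geometryParams(stenosisDegree = 0)
  xs <- seq(0, p0@lProx, length.out = 101)
  expect_equal(stenosisProfile(xs, p0), rep(4.5e-3, 101))
  for (deg in c(0.3, 0.5, 0.75, 1)) {
    p <- geometryParams(stenosisDegree = deg)
    expect_equal(stenosisProfile(p@xSten, p), 4.5e-3 * (1 - deg))
  }
})

test_that("stenosis profile is symmetric, continuous and C1 at bump edges", {
  p <- geometryParams(stenosisDegree = 0.6)
  d <- seq(0, p@lSten / 2, length.out = 200)
  expect_equal(stenosisProfile(p@xSten + d, p), stenosisProfile(p@xSten - d, p))
  ## minimum equals dLad (1 - degree) to machine precision
  xs <- seq(0, p@lProx, length.out = 5001)
  expect_equal(min(stenosisProfile(xs, p)), p@dLad * (1 - 0.6),
               tolerance = 1e-14)
  ## numerical derivative vanishes at the bump boundaries (C1 match)
  eps <- 1e-7
  for (xe in p@xSten + c(-1, 1) * p@lSten / 2) {
    dd <- (stenosisProfile(xe + eps, p) - stenosisProfile(xe - eps, p)) / (2 * eps)
    expect_lt(abs(dd), 1e-4)
  }
})

test_that("invalid geometry parameters are rejected", {
  expect_error(geometryParams(stenosisDegree = 1.2), "stenosisDegree")
  expect_error(geometryParams(dLad = -1), "positive")
  expect_error(geometryParams(angle = 95), "angle")
  ## bump overlapping the junction
  expect_error(buildGeometry(geometryParams(xSten = 0.044, lSten = 0.01)),
               "stenosis bump")
})

test_that("outline topology follows the stenosis degree", {
  o0 <- buildGeometry(geometryParams(stenosisDegree = 0))
  tags0 <- vapply(o0$segments, `[[`, "", "tag")
  expect_setequal(setdiff(unique(tags0), "WALL"),
                  c("LAD_INLET", "GRAFT_INLET", "OUTLET"))
  o1 <- buildGeometry(geometryParams(stenosisDegree = 1))
  tags1 <- vapply(o1$segments, `[[`, "", "tag")
  expect_setequal(setdiff(unique(tags1), "WALL"), c("GRAFT_INLET", "OUTLET"))
})

test_that("junction opening length matches plane trigonometry", {
  ## two wall lines at 45 degrees intersecting a channel of width 4.6 mm cut
  ## an opening of dGraft / sin(angle) out of the LAD wall
  o <- buildGeometry(geometryParams())
  expect_equal(o$junction$xt - o$junction$xh, 4.6e-3 / sin(45 * pi / 180),
               tolerance = 1e-12)
  ## independent check: intersect the two graft wall lines with y = dLad
  J <- o$junction
  lineX <- function(P, dir) P[1] + (4.5e-3 - P[2]) / dir[2] * dir[1]
  xHeel <- lineX(J$P1, J$axis); xToe <- lineX(J$P2, J$axis)
  expect_equal(xToe - xHeel, J$opening, tolerance = 1e-12)
})
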