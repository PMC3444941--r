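## Frozen oracle values: 2A/pi for the rectified sinusoid (closed form) and
## hand integrals for the piecewise series (+1 Pa for 0.6 s, -1 Pa for 0.2 s:
## int |tau| = 0.8, |int tau| = 0.4, OSI = 0.5 (1 - 0.5) = 0.25).

test_that("TAWSS matches closed forms on analytic series", {
  ex <- exampleShearSeries()
  tt <- ex$sine@times
  expect_equal(tawss(shearSeries(tt, rep(0.2, length(tt)))), 0.2,
               tolerance = 1e-12)
  expect_equal(tawss(ex$sine), 2 * 0.3 / pi, tolerance = 1e-5)
  expect_equal(tawss(ex$piecewise), 1, tolerance = 1e-9)
})

test_that("OSI hits its definitional limits and hand values", {
  ex <- exampleShearSeries()
  expect_equal(osi(ex$sine), 0.5, tolerance = 1e-10)
  expect_equal(osi(ex$unidir), 0, tolerance = 1e-10)
  expect_equal(osi(ex$piecewise), 0.25, tolerance = 1e-9)
  ## identically zero shear: defined as the unidirectional limit
  tt <- ex$sine@times
  expect_equal(osi(shearSeries(tt, numeric(length(tt)))), 0)
})

test_that("quadrature agrees with dense Riemann sums on the example series", {
  N <- 1e5
  T <- 0.8
  tm <- (seq_len(N) - 0.5) * T / N       # midpoint rule abscissae
  riemann <- function(f) sum(f(tm)) * (T / N) / T
  cases <- list(
    sine = list(f = function(t) 0.3 * sin(2 * pi * t / T)),
    unidir = list(f = function(t) 0.1 + 0.05 * sin(2 * pi * t / T)),
    piecewise = list(f = function(t) ifelse(t < 0.6, 1, -1)))
  dense <- exampleShearSeries(times = seq(0, T, length.out = N + 1))
  for (nm in names(cases)) {
    f <- cases[[nm]]$f
    tawssOracle <- riemann(function(t) abs(f(t)))
    osiOracle <- 0.5 * (1 - abs(riemann(f)) / riemann(function(t) abs(f(t))))
    expect_equal(tawss(dense[[nm]]), tawssOracle, tolerance = 1e-6)
    expect_equal(osi(dense[[nm]]), osiOracle, tolerance = 1e-6)
  }
})

test_that("TAWSS and OSI are invariant under rigid rotation of the shear vectors", {
  set.seed(42)
  tt <- seq(0, 0.8, by = 0.002)
  for (rep in 1:5) {
    tx <- rbind(0.1 * sin(2 * pi * tt / 0.8) + rnorm(1, 0, 0.05))
    ty <- rbind(0.04 * cos(4 * pi * tt / 0.8) + rnorm(1, 0, 0.02))
    th <- runif(1, 0, 2 * pi)
    rot <- shearSeries(tt, cos(th) * tx - sin(th) * ty,
                       sin(th) * tx + cos(th) * ty)
    base <- shearSeries(tt, tx, ty)
    expect_equal(tawss(rot), tawss(base), tolerance = 1e-12)
    expect_equal(osi(rot), osi(base), tolerance = 1e-12)
  }
})

test_that("OSI stays in [0, 0.5] and TAWSS nonnegative over random series", {
  set.seed(7)
  tt <- seq(0, 0.8, by = 0.004)
  for (rep in 1:25) {
    k <- sample(1:6, 1)
    tx <- rbind(colSums(matrix(rnorm(k * length(tt)) *
                  sin(2 * pi * outer(1:k, tt / 0.8) + rnorm(k)), k)))
    ty <- rbind(colSums(matrix(rnorm(k * length(tt)) *
                  cos(2 * pi * outer(1:k, tt / 0.8) + rnorm(k)), k)))
    s <- shearSeries(tt, tx, ty)
    expect_gte(tawss(s), 0)
    expect_gte(osi(s), 0)
    expect_lte(osi(s), 0.5)
  }
})

test_that("wall shear extraction recovers a linear shear layer", {
  ## near-wall layer u_t = gamma d with gamma = 10 1/s -> |tau| = mu gamma
  mesh <- channelMesh(1e-3, 2e-3, targetH = 2.5e-4, refineWall = 1)
  ops <- graftflow:::lightOperators(mesh, fluidProps())
  sol <- new("FlowSolution", mesh = mesh, times = c(0, 0.4, 0.8),
             u = matrix(10 * mesh@nodes[, 2], nrow(mesh@nodes), 3),
             v = matrix(0, nrow(mesh@nodes), 3),
             p = matrix(0, nrow(mesh@nodes), 3),
             wallTraces = list(), periodicityError = list(),
             diagnostics = list())
  ser <- wallShearSeries(sol, "CHANNEL_WALL")
  expect_equal(unname(as.vector(sqrt(ser@tauX^2 + ser@tauY^2))),
               rep(0.0035 * 10, length(ser@s) * 3), tolerance = 1e-10)
  ## tangentiality
  dotn <- abs(ser@tauX * ser@normals[, 1] + ser@tauY * ser@normals[, 2])
  expect_lt(max(dotn / pmax(sqrt(ser@tauX^2 + ser@tauY^2), 1e-30)), 1e-10)
})

test_that("Reynolds number and Poiseuille reference follow their formulas", {
  expect_equal(reynoldsNumber(0.7609, 4.6e-3), 1050, tolerance = 1e-3)
  expect_equal(reynoldsNumber(0, 4.6e-3), 0)
  expect_equal(reynoldsNumber(0.2, 4.6e-3), 2 * reynoldsNumber(0.1, 4.6e-3))
  expect_equal(poiseuilleReference(0.03, 4.6e-3), 6 * 0.0035 * 0.03 / 4.6e-3)
  expect_equal(poiseuilleReference(0, 4.6e-3), 0)
  expect_equal(poiseuilleReference(0.03, 2.3e-3),
               2 * poiseuilleReference(0.03, 4.6e-3))
  expect_error(poiseuilleReference(0.03, 0), "positive")
})

test_that("missing wall regions are reported", {
  mesh <- channelMesh(1e-3, 2e-3, targetH = 5e-4)
  sol <- new("FlowSolution", mesh = mesh, times = c(0, 0.8),
             u = matrix(0, nrow(mesh@nodes), 2),
             v = matrix(0, nrow(mesh@nodes), 2),
             p = matrix(0, nrow(mesh@nodes), 2),
             wallTraces = list(), periodicityError = list(),
             diagnostics = list())
  expect_error(wallShearSeries(sol, "GRAFT_WALL"), "missing region")
})
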