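test_that("zero inflow and zero state is a fixed point", {
  mesh <- channelMesh(1e-3, 2e-3, targetH = 2.5e-4, refineWall = 1)
  ops <- assembleOperators(mesh, fluidProps())
  bcs <- function(t) list(nodes = ops$dirNodes,
                          ux = numeric(length(ops$dirNodes)),
                          uy = numeric(length(ops$dirNodes)))
  st <- stepFlow(newFlowState(ops), 0, bcs, solverConfig(), ops)
  expect_equal(max(abs(st$u), abs(st$v)), 0)
})

test_that("steady channel flow reproduces planar Poiseuille", {
  ss <- getSteadyChannel()
  st <- ss$state; ops <- ss$ops
  ## centerline / mean ratio 1.5 within 2%
  expect_equal(max(st$u) / 0.03, 1.5, tolerance = 0.02)
  ## wall shear 6 mu v / H within 2% away from the ends
  sel <- ops$bedge$tag == "WALL" & abs(ops$bedge$mx - ss$xMid) < 3e-3
  tw <- graftflow:::wallTraction(ops, st$u, st$v, sel)
  tauRef <- 6 * 0.0035 * 0.03 / 4.5e-3
  expect_equal(mean(sqrt(tw$tx^2 + tw$ty^2)), tauRef, tolerance = 0.02)
  ## transverse velocity negligible
  expect_lt(max(abs(st$v)), 2e-3 * max(st$u))
})

test_that("each step closes the global mass balance", {
  mesh <- generateMesh(buildGeometry(geometryParams(stenosisDegree = 0.5)),
                       targetH = 1e-3)
  ops <- assembleOperators(mesh, fluidProps())
  cond <- canonicalConditions()$reduced
  bcs <- graftflow:::conditionBC(ops, cond)
  cfg <- solverConfig()
  st <- newFlowState(ops)
  for (k in 1:25) {
    st <- stepFlow(st, (k - 1) * cfg@dt, bcs, cfg, ops)
    influx <- abs(graftflow:::boundaryFlux(
      ops, st$u, st$v, ops$bedge$tag %in% c("LAD_INLET", "GRAFT_INLET")))
    expect_lt(abs(st$fluxImbalance) / influx, 1e-6)
    ## weak divergence at interior pressure nodes at solver tolerance
    expect_lt(st$divResidual / influx, 1e-6)
  }
})

test_that("kinetic energy decays monotonically once inlets are shut", {
  ss <- getSteadyChannel()
  ops <- ss$ops
  st <- ss$state
  bcs0 <- function(t) list(nodes = ops$dirNodes,
                           ux = numeric(length(ops$dirNodes)),
                           uy = numeric(length(ops$dirNodes)))
  ## also zero the (Dirichlet) inlet immediately
  st$u[ops$dirNodes] <- 0; st$v[ops$dirNodes] <- 0
  cfg <- solverConfig()
  ke <- kineticEnergy(ops, st)
  for (k in 1:40) {
    st <- stepFlow(st, (k - 1) * cfg@dt, bcs0, cfg, ops)
    keNew <- kineticEnergy(ops, st)
    expect_lte(keNew, ke * (1 + 1e-12))
    ke <- keNew
  }
})

test_that("identical configurations give bitwise-identical solutions", {
  mesh <- generateMesh(buildGeometry(geometryParams(stenosisDegree = 1)),
                       targetH = 1.2e-3)
  cond <- canonicalConditions()$none
  cfg <- solverConfig(cycles = 2, spinupCycles = 0, outputStride = 8)
  s1 <- runSimulation(mesh, cond, fluidProps(), cfg)
  s2 <- runSimulation(mesh, cond, fluidProps(), cfg)
  expect_identical(s1@u, s2@u)
  expect_identical(s1@p, s2@p)
  expect_identical(s1@periodicityError, s2@periodicityError)
})

test_that("steady waveforms yield an essentially periodic solution at once", {
  mesh <- generateMesh(buildGeometry(geometryParams(stenosisDegree = 0.5)),
                       targetH = 1.2e-3)
  cond <- canonicalConditions()$reduced
  steadyCond <- new("ConditionSpec", name = "reduced", stenosisDegree = 0.5,
                    ladWaveform = makeWaveform(cond@ladWaveform@meanVelocity, 0),
                    graftWaveform = makeWaveform(cond@graftWaveform@meanVelocity, 0))
  sol <- runSimulation(mesh, steadyCond, fluidProps(),
                       solverConfig(cycles = 2, spinupCycles = 0))
  expect_lt(sol@periodicityError$pressure, 1e-8)
  expect_lt(sol@periodicityError$wss, 1e-8)
})

test_that("the oscillatory channel benchmark matches the closed form", {
  res <- womersleyBenchmark()
  expect_equal(res$alpha, 2.25e-3 * sqrt(2 * pi / 0.8 * 1050 / 0.0035),
               tolerance = 1e-12)
  expect_equal(res$alpha, 3.45, tolerance = 0.01)
  expect_lt(res$maxRelError, 0.05)
})

test_that("field export round-trips bit-identically", {
  mesh <- generateMesh(buildGeometry(geometryParams(stenosisDegree = 1)),
                       targetH = 1.2e-3)
  cond <- canonicalConditions()$none
  sol <- runSimulation(mesh, cond, fluidProps(),
                       solverConfig(cycles = 2, spinupCycles = 0,
                                    outputStride = 100))
  dir <- tempfile()
  idx <- exportFieldsVTK(sol, dir)
  files <- list.files(dir, pattern = "\\.vtk$", full.names = TRUE)
  expect_length(files, length(sol@times))
  back <- readFieldsVTK(files[2])
  expect_identical(back$u, unname(sol@u[, 2]))
  expect_identical(back$p, unname(sol@p[, 2]))
  expect_identical(back$points[, 1], unname(mesh@nodes[, 1]))
  unlink(dir, recursive = TRUE)
})
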