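test_that("zero pulse amplitude gives a constant waveform", {
  w <- makeWaveform(0.03, 0)
  tt <- seq(0, 0.8, length.out = 57)
  expect_equal(waveformVelocity(w, tt), rep(0.03, 57))
})

test_that("waveforms integrate to their declared mean and are periodic", {
  cases <- list(
    makeWaveform(0.03, 0.05),
    makeWaveform(0.049, 0.07),
    makeWaveform(0.012, 0.03, reverseWindow = rbind(c(0, 0.07), c(0.73, 0.8)),
                 reverseDepth = 0.01))
  for (w in cases) {
    tt <- seq(0, 0.8, by = 0.001)
    v <- waveformVelocity(w, tt)
    trap <- sum((v[-1] + v[-length(v)]) / 2 * diff(tt)) / 0.8
    expect_equal(trap, w@meanVelocity, tolerance = 1e-10)
    expect_equal(waveformVelocity(w, tt), waveformVelocity(w, tt + 0.8),
                 tolerance = 1e-12)
    ## C1: finite-difference derivative has no jumps beyond curvature scale
    expect_true(all(is.finite(diff(v, differences = 2))))
  }
})

test_that("reverse windows force reverse flow at the cycle start and end", {
  w <- makeWaveform(0.02, 0.04,
                    reverseWindow = rbind(c(0, 0.05), c(0.75, 0.8)))
  expect_lt(waveformVelocity(w, 0.025), 0)
  expect_lt(waveformVelocity(w, 0.775), 0)
  expect_gt(reverseFraction(w), 0)
})

test_that("infeasible reverse calibrations are rejected", {
  expect_error(makeWaveform(0.02, 0.04, reverseWindow = rbind(c(0, 0.5))),
               "infeasible|invalid")
  expect_error(makeWaveform(0.02, 0.04, reverseWindow = rbind(c(0.3, 0.1))),
               "invalid reverse window")
})

test_that("canonical conditions satisfy the competitive-flow structure", {
  conds <- canonicalConditions()
  expect_length(conds, 5)
  expect_equal(vapply(conds, slot, 0, "stenosisDegree"),
               c(higher = 0, secondary = 0.3, reduced = 0.5, lower = 0.75,
                 none = 1))
  mG <- vapply(conds, function(cd) cd@graftWaveform@meanVelocity, 0)
  expect_true(all(diff(mG) > 0))
  mL <- vapply(conds[1:4], function(cd) cd@ladWaveform@meanVelocity, 0)
  expect_true(all(diff(mL) < 0))
  expect_null(conds$none@ladWaveform)
  ## fixed total mean inflow rate across conditions (within 1%)
  rates <- vapply(conds, function(cd) {
    g <- cd@graftWaveform@meanVelocity * 4.6e-3
    l <- if (is.null(cd@ladWaveform)) 0 else
      cd@ladWaveform@meanVelocity * 4.5e-3
    g + l
  }, 0)
  expect_lt(diff(range(rates)) / mean(rates), 0.01)
  ## reverse flow iff stenosis < 50%
  rf <- vapply(conds, function(cd) reverseFraction(cd@graftWaveform), 0)
  expect_identical(unname(rf > 0), c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("identical calibrations give bitwise-identical waveforms", {
  c1 <- canonicalConditions(); c2 <- canonicalConditions()
  for (i in seq_along(c1)) {
    expect_identical(c1[[i]]@graftWaveform@cosCoef, c2[[i]]@graftWaveform@cosCoef)
    expect_identical(c1[[i]]@graftWaveform@sinCoef, c2[[i]]@graftWaveform@sinCoef)
  }
})

test_that("inlet profiles are parabolic, no-slip compatible and reversible", {
  mesh <- channelMesh(4.6e-3, 0.01, targetH = 4e-4)
  w <- makeWaveform(0.1, 0)
  pr <- inletProfile(w, 0, mesh, "LAD_INLET")
  geo <- graftflow:::inletGeometry(mesh, "LAD_INLET")
  expect_equal(pr$ux, 6 * 0.1 * geo$zeta * (1 - geo$zeta))
  expect_equal(max(pr$ux), 0.15, tolerance = 0.02)  # planar peak = 1.5 mean
  ends <- geo$zeta %in% c(0, 1)
  expect_true(all(pr$ux[ends] == 0))
  prNeg <- inletProfile(makeWaveform(-0.1, 0), 0, mesh, "LAD_INLET")
  expect_true(all(prNeg$ux[!ends] < 0))
})
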