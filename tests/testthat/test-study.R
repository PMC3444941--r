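test_that("percent change follows its definition", {
  ## arithmetic consistency of the reported band endpoints: 0.1 Pa against a
  ## reference of ~0.234 Pa is a 57.3% decrease
  expect_equal(percentChange(0.1, 0.2342), -57.3, tolerance = 1e-3)
  expect_equal(percentChange(5, 5), 0)
  expect_equal(percentChange(2, 1), 100)
  expect_error(percentChange(1, 0), "zero reference")
})

test_that("the five-condition study reproduces the competitive-flow contrasts", {
  res <- getDefaultStudy()
  cmp <- res@comparison
  expect_equal(nrow(cmp), 5)
  expect_equal(cmp$stenosis, c(0, 0.3, 0.5, 0.75, 1))
  ## reference row compares to itself exactly
  expect_identical(cmp$pctTAWSS[cmp$condition == "none"], 0)
  expect_identical(cmp$pctOSI[cmp$condition == "none"], 0)
  ## the headline orderings
  expect_true(res@trends$tawssIncreasing)
  expect_true(res@trends$osiDecreasing)
  ## percent changes signed as expected: TAWSS lower, OSI higher than the
  ## no-competitive-flow reference everywhere
  nonRef <- cmp$condition != "none"
  expect_true(all(cmp$pctTAWSS[nonRef] < 0))
  expect_true(all(cmp$pctOSI[nonRef] > 0))
  ## solver-vs-waveform Reynolds consistency: the measured peak graft inlet
  ## speed should match 1.5x the waveform peak within 5%
  conds <- canonicalConditions()
  for (i in seq_len(5)) {
    reWave <- reynoldsNumber(1.5 * peakVelocity(conds[[i]]@graftWaveform),
                             4.6e-3)
    expect_equal(cmp$reynoldsMax[i], reWave, tolerance = 0.05)
  }
})

test_that("study report files carry the full schema", {
  res <- getDefaultStudy()
  dir <- tempfile()
  studyReport(res, dir)
  cmp <- read.csv(file.path(dir, "comparison.csv"), comment.char = "#")
  expect_equal(nrow(cmp), 5)
  expect_true(all(c("condition", "stenosis", "graftMeanTAWSS", "graftMeanOSI",
                    "tau0", "reynoldsMax", "periodicityP", "periodicityWSS",
                    "pctTAWSS", "pctOSI") %in% names(cmp)))
  rpt <- readLines(file.path(dir, "report.txt"))
  expect_true(any(grepl("Reynolds", rpt)))
  expect_true(any(grepl("periodicity", rpt)))
  expect_true(any(grepl("2D planar", rpt)))
  for (nm in names(res@metrics))
    expect_true(file.exists(file.path(dir, sprintf("metrics_%s.csv", nm))))
  unlink(dir, recursive = TRUE)
})

test_that("mesh sensitivity handles degenerate level lists", {
  expect_error(meshSensitivityReport(levels = c(3e-4, 3e-4)), "decreasing")
  one <- meshSensitivityReport(levels = 1.2e-3)
  expect_equal(nrow(one), 1)
  expect_true(is.na(one$relChangeWSS[1]))
  expect_true(is.na(one$converged[1]))
})
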