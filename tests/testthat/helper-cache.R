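## Heavy shared computations, run once per test session.
.gfCache <- new.env(parent = emptyenv())

getDefaultStudy <- function() {
  if (is.null(.gfCache$study))
    .gfCache$study <- runStudy(studyConfig())
  .gfCache$study
}

getSensitivity <- function() {
  if (is.null(.gfCache$sens))
    .gfCache$sens <- meshSensitivityReport(levels = c(6e-4, 3e-4, 1.5e-4))
  .gfCache$sens
}

getSteadyChannel <- function() {
  if (is.null(.gfCache$chan)) {
    ## even cross-cell count puts a node on the centerline
    mesh <- channelMesh(4.5e-3, 0.018, targetH = 2.5e-4)
    .gfCache$chan <- c(solveSteady(mesh, fluidProps(), vLad = 0.03),
                       list(xMid = 0.009))
  }
  .gfCache$chan
}

## Analytic shear series of the three canonical quadrature examples, sampled
## on a given time grid (defaults to the solver grid).
exampleShearSeries <- function(times = seq(0, 0.8, by = 0.001)) {
  T <- 0.8
  sine <- shearSeries(times, tauX = 0.3 * sin(2 * pi * times / T))
  unidir <- shearSeries(times, tauX = 0.1 + 0.05 * sin(2 * pi * times / T))
  ## piecewise +1 Pa for 0.6 s then -1 Pa; duplicate the jump abscissae so
  ## trapezoidal quadrature integrates the steps exactly
  tj <- sort(unique(c(times, 0.6 - 1e-12, 0.6 + 1e-12)))
  pw <- ifelse(tj < 0.6 - 5e-13, 1, ifelse(tj > 0.6 + 5e-13, -1, 1))
  pw[tj >= 0.6 + 5e-13] <- -1
  piecewise <- shearSeries(tj, tauX = pw)
  list(sine = sine, unidir = unidir, piecewise = piecewise)
}
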