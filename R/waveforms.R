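## Fourier machinery for synthetic coronary inlet waveforms.
##
## Waveforms are truncated Fourier series fitted to smooth lobe templates:
## a diastolic-dominant two-lobe coronary pattern, optionally a narrow
## high-velocity spike, and raised-cosine reverse-flow dips at prescribed
## windows.  The constant term is set to the requested cycle mean exactly, so
## quadrature of the closed-form series reproduces the mean to machine
## precision.

## Periodic raised-cosine bump of unit height, center cc and full width ww
## (both in units of the period).
.bumpEval <- function(tt, cc, ww) {
  d <- (tt - cc) %% 1
  d[d > 0.5] <- d[d > 0.5] - 1
  out <- numeric(length(tt))
  inside <- abs(d) <= ww / 2
  out[inside] <- cos(pi * d[inside] / ww)^2
  out
}

## Project a sampled periodic signal (uniform fine grid over one period,
## endpoint excluded) onto K harmonics.  Returns list(a0, cos, sin).
.fourierProject <- function(f, K) {
  n <- length(f)
  tt <- (seq_len(n) - 1) / n
  a0 <- mean(f)
  ks <- seq_len(K)
  cosM <- cos(2 * pi * outer(tt, ks))
  sinM <- sin(2 * pi * outer(tt, ks))
  list(a0 = a0,
       cos = as.vector(crossprod(cosM, f)) * 2 / n,
       sin = as.vector(crossprod(sinM, f)) * 2 / n)
}

## Evaluate a harmonic set at relative times tt (units of the period).
.fourierEval <- function(coefs, tt) {
  ks <- seq_along(coefs$cos)
  ang <- 2 * pi * outer(tt, ks)
  as.vector(coefs$a0 + cos(ang) %*% coefs$cos + sin(ang) %*% coefs$sin)
}

.defaultLobes <- function() {
  ## center, full width, height (relative units): small systolic lobe and a
  ## dominant diastolic lobe, low at the cycle ends
  rbind(c(0.19, 0.30, 0.35),
        c(0.56, 0.44, 1.00))
}

#' Construct a synthetic periodic inlet waveform
#'
#' Builds a smooth diastolic-dominant coronary-type velocity signal as a
#' truncated Fourier series: lobe templates (two-lobe pattern by default, or
#' caller-supplied lobes, e.g. adding a narrow high-velocity spike) are
#' projected onto \code{nHarmonics} harmonics, scaled so the peak deviation
#' above the mean equals \code{pulseAmplitude}, and, if reverse windows are
#' given, zero-mean raised-cosine dips are added and scaled so the signal is
#' negative across the central part of each window.
#'
#' @param meanVelocity cycle-mean velocity (m/s); reproduced exactly.
#' @param pulseAmplitude peak excursion above the mean (m/s, >= 0).
#' @param reverseWindow \code{NULL}, or a 2-column matrix of [start, end]
#'   times (s) inside which the flow must reverse.
#' @param period cycle duration (s).
#' @param nHarmonics number of Fourier harmonics retained.
#' @param lobes lobe template matrix (center, width, height in period units).
#' @param reverseDepth target negative velocity (m/s, positive number) at the
#'   reverse-window centers; default 25% of the waveform scale.
#' @return A \code{Waveform}.
#' @export
makeWaveform <- function(meanVelocity, pulseAmplitude = 0,
                         reverseWindow = NULL, period = 0.8,
                         nHarmonics = 32, lobes = .defaultLobes(),
                         reverseDepth = NULL) {
  if (period <= 0) stop("period must be positive")
  if (pulseAmplitude < 0) stop("pulseAmplitude must be non-negative")
  n <- 4096
  tt <- (seq_len(n) - 1) / n
  if (pulseAmplitude > 0) {
    shape <- rowSums(vapply(seq_len(nrow(lobes)), function(i)
      lobes[i, 3] * .bumpEval(tt, lobes[i, 1], lobes[i, 2]),
      numeric(n)))
    co <- .fourierProject(shape, nHarmonics)
    co$a0 <- 0                                # zero-mean lobe component
    samp <- .fourierEval(co, tt)
    sc <- pulseAmplitude / max(samp)
    co$cos <- co$cos * sc; co$sin <- co$sin * sc
  } else {
    co <- list(a0 = 0, cos = numeric(nHarmonics), sin = numeric(nHarmonics))
  }
  rw <- matrix(numeric(0), 0, 2)
  if (!is.null(reverseWindow)) {
    rw <- matrix(reverseWindow, ncol = 2)
    if (any(rw[, 2] <= rw[, 1]) || any(rw < 0) || any(rw > period))
      stop("invalid reverse window")
    if (sum(rw[, 2] - rw[, 1]) > 0.5 * period)
      stop("infeasible calibration: reverse windows cover over half the cycle")
    scale <- max(abs(meanVelocity), pulseAmplitude, 1e-3)
    depth <- if (is.null(reverseDepth)) 0.25 * scale else reverseDepth
    dip <- rowSums(vapply(seq_len(nrow(rw)), function(i) {
      cc <- mean(rw[i, ]) / period
      ww <- (rw[i, 2] - rw[i, 1]) / period
      .bumpEval(tt, cc, ww)
    }, numeric(n)))
    cd <- .fourierProject(dip, nHarmonics)
    cd$a0 <- 0
    dipS <- .fourierEval(cd, tt)
    ## scale so the signal sits at -depth where the dip is strong
    band <- dipS > 0.5 * max(dipS)
    base <- meanVelocity + .fourierEval(co, tt)
    cNeed <- max(0, (base[band] + depth) / dipS[band])
    if (!is.finite(cNeed))
      stop("infeasible calibration: reverse window incompatible with the mean")
    if (cNeed * max(dipS) > 60 * scale)
      stop("infeasible calibration: required reverse dip is unreasonably deep")
    co$cos <- co$cos - cNeed * cd$cos
    co$sin <- co$sin - cNeed * cd$sin
  }
  new("Waveform", period = period, meanVelocity = meanVelocity,
      cosCoef = co$cos, sinCoef = co$sin, reverseWindows = rw)
}

#' Evaluate a waveform
#'
#' Closed-form evaluation of the Fourier series at arbitrary times; exactly
#' periodic by construction.
#'
#' @param w a \code{Waveform}.
#' @param t times (s); vectorized.
#' @return Cross-section-mean velocities (m/s).
#' @export
waveformVelocity <- function(w, t) {
  ks <- seq_along(w@cosCoef)
  ang <- 2 * pi * outer(t / w@period, ks)
  as.vector(w@meanVelocity + cos(ang) %*% w@cosCoef + sin(ang) %*% w@sinCoef)
}

#' @describeIn waveformVelocity fraction of the cycle with reverse flow
#' @export
reverseFraction <- function(w) {
  tt <- seq(0, w@period, length.out = 4001)[-4001]
  mean(waveformVelocity(w, tt) < 0)
}

#' Peak velocity over the cycle
#' @param w a \code{Waveform}.
#' @return max over the cycle of v(t) (m/s).
#' @export
peakVelocity <- function(w) {
  tt <- seq(0, w@period, length.out = 4001)
  max(waveformVelocity(w, tt))
}

#' @export
setMethod("show", "Waveform", function(object) {
  cat(sprintf(
    "Waveform: period %.3g s, mean %.4g m/s, peak %.4g m/s, %d harmonics, reverse fraction %.3f\n",
    object@period, object@meanVelocity, peakVelocity(object),
    length(object@cosCoef), reverseFraction(object)))
})

#' Sample a waveform to a data frame
#' @param w a \code{Waveform}.
#' @param dt sample spacing (s).
#' @return data.frame with columns t (s) and v (m/s).
#' @export
waveformTable <- function(w, dt = 0.001) {
  t <- seq(0, w@period, by = dt)
  data.frame(t = t, v = waveformVelocity(w, t))
}

#' Parabolic inlet velocity profile on a tagged inlet
#'
#' Returns the planar-Poiseuille (parabolic) velocity vectors on the nodes of
#' an inlet boundary: zero at the wall-adjacent endpoints, 1.5 times the
#' cross-section mean at the centerline, directed inward along the channel
#' axis.  A negative instantaneous mean yields an outward-directed (reverse)
#' profile.
#'
#' @param w a \code{Waveform}.
#' @param t time (s).
#' @param mesh a \code{TriMesh}.
#' @param tag \code{"LAD_INLET"} or \code{"GRAFT_INLET"}.
#' @return list(nodes = node indices, ux =, uy = velocity components).
#' @export
inletProfile <- function(w, t, mesh, tag) {
  bc <- inletGeometry(mesh, tag)
  vmean <- waveformVelocity(w, t)
  mag <- 6 * vmean * bc$zeta * (1 - bc$zeta)
  list(nodes = bc$nodes, ux = mag * bc$dir[1], uy = mag * bc$dir[2])
}

## Inlet node set, normalized cross-span coordinate zeta in [0,1], and inward
## flow direction for a tagged inlet.
inletGeometry <- function(mesh, tag) {
  sel <- mesh@boundaryTag == tag
  if (!any(sel)) stop(sprintf("no boundary edges tagged %s", tag))
  nodes <- sort(unique(as.vector(mesh@boundaryEdges[sel, ])))
  pts <- mesh@nodes[nodes, , drop = FALSE]
  if (tag == "GRAFT_INLET") {
    dir <- mesh@meta$junction$axis
  } else {
    dir <- c(1, 0)                      # LAD/channel axis
  }
  tang <- c(-dir[2], dir[1])
  s <- pts %*% tang
  zeta <- as.vector((s - min(s)) / (max(s) - min(s)))
  list(nodes = nodes, zeta = zeta, dir = dir)
}
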