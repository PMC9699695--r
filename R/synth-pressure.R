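#' Synthetic pressure/box series with a planted edge tension
#'
#' Emulates the fixed-edge open-membrane protocol: the box length along
#' the open edge is fixed, the two lateral dimensions are pressure
#' coupled, and the edge tension is read from the stationary anisotropy
#' of the pressure tensor.  `Pxx` and `Pyy` are drawn i.i.d. around
#' 1 bar and `Pzz` around `1 - delta`, with `delta` chosen so that the
#' expectation of the two-edge estimator equals `gammaTrue`:
#' `delta = nEdges * gammaTrue / (0.1 * boxXY^2)` bar.
#'
#' @param gammaTrue planted edge tension in pN (negative values are
#'   allowed -- edge compression -- and flagged with a warning).
#' @param boxXY lateral box length in nm (Lx = Ly, constant).
#' @param noiseSd white-noise standard deviation of each pressure
#'   component, in bar.
#' @param nFrames number of frames (>= 1).
#' @param seed RNG seed.
#' @param dt frame spacing in ns.
#' @param nEdges number of open edges assumed by the matching estimator.
#' @return a [PressureBoxSeries] with a `groundTruth` attribute.
#' @examples
#' s <- synthPressureSeries(86.4, boxXY = 20, noiseSd = 0, nFrames = 10,
#'                          seed = 1)
#' tension(edgeTension(s))  # 86.4
#' @export
synthPressureSeries <- function(gammaTrue, boxXY = 20, noiseSd = 0,
                                nFrames = 1000L, seed = NULL, dt = 0.01,
                                nEdges = 2L) {
  stopifnot(boxXY > 0, nFrames >= 1)
  if (gammaTrue < 0)
    warning("gammaTrue < 0: planting an edge under compression")
  delta <- nEdges * gammaTrue / (BAR_NM2_TO_PN * boxXY^2)
  withSeed(seed, {
    Pxx <- rnorm(nFrames, 1, noiseSd)
    Pyy <- rnorm(nFrames, 1, noiseSd)
    Pzz <- rnorm(nFrames, 1 - delta, noiseSd)
  })
  out <- new("PressureBoxSeries",
             time = (seq_len(nFrames) - 1L) * dt,
             Pxx = Pxx, Pyy = Pyy, Pzz = Pzz,
             Lx = rep(boxXY, nFrames), Ly = rep(boxXY, nFrames))
  attr(out, "groundTruth") <- list(
    generator = "synth_pressure_series", seed = seed,
    gammaTrue = gammaTrue, boxXY = boxXY, noiseSd = noiseSd,
    nFrames = nFrames, nEdges = nEdges, delta = delta)
  out
}
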