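#' Synthetic ion z-trajectories with known crossing counts
#'
#' Builds per-ion z(t) paths relative to a membrane slab
#' `[zLow, zHigh]` inside a periodic box of height `Lz`.  Path types:
#' \describe{
#'   \item{full_up}{starts below the slab, traverses it, ends above:
#'     one up event.}
#'   \item{full_down}{the mirror image: one down event.}
#'   \item{rebound}{enters the slab from below and exits the same side:
#'     no event.}
#'   \item{boundary_dither}{oscillates many times across the lower
#'     boundary without ever reaching the upper one: no event.}
#'   \item{pbc_wrapped_cross}{a full upward traversal whose tail then
#'     wraps through the periodic z boundary: exactly one up event once
#'     the path is unwrapped.}
#' }
#' All step sizes are kept well below `Lz/2` except the deliberate
#' periodic wrap.
#'
#' @param plan data.frame with columns `species` (e.g. "NA"/"CL") and
#'   `type` (one of the path types above); one row per ion.
#' @param slab numeric length-2 `(zLow, zHigh)` in nm.
#' @param nFrames frames per path (>= 40).
#' @param Lz box height in nm (> zHigh).
#' @param noiseSd added white noise in nm (kept small; 0 disables).
#' @param seed RNG seed.
#' @return list(z, plan, truth): `z` an ions x frames matrix of wrapped
#'   coordinates in [0, Lz); `truth` per-ion planted (up, down) counts.
#'   Carries a `groundTruth` attribute.
#' @export
synthIonPaths <- function(plan, slab, nFrames = 200L, Lz = 12,
                          noiseSd = 0.02, seed = NULL) {
  zLow <- slab[1L]; zHigh <- slab[2L]
  stopifnot(zLow < zHigh, zHigh < Lz, nFrames >= 40L)
  types <- c("full_up", "full_down", "rebound", "boundary_dither",
             "pbc_wrapped_cross")
  stopifnot(all(plan$type %in% types))
  nIon <- nrow(plan)
  half <- nFrames %/% 2L

  mkPath <- function(type) {
    below <- max(zLow - 1.5, 0.2)
    above <- min(zHigh + 1.0, Lz - 0.4)
    switch(type,
      full_up = approx(c(1, nFrames), c(below, above), n = nFrames)$y,
      full_down = approx(c(1, nFrames), c(above, below), n = nFrames)$y,
      rebound = c(approx(c(1, half), c(below, (zLow + zHigh) / 2),
                         n = half)$y,
                  approx(c(1, nFrames - half),
                         c((zLow + zHigh) / 2, below),
                         n = nFrames - half)$y),
      boundary_dither = zLow +
        0.3 * sin(seq(0, 50 * pi, length.out = nFrames)),
      pbc_wrapped_cross = {
        ## unwrapped: below -> above -> keeps rising past Lz into the
        ## next periodic image (but not far enough to reach the slab's
        ## image); wrapped, the tail jumps from ~Lz to ~0
        up <- approx(c(1, half), c(below, above), n = half)$y
        tailEnd <- Lz + max(zLow - 1.0, 0.1)
        tl <- approx(c(1, nFrames - half), c(above, tailEnd),
                     n = nFrames - half)$y
        c(up, tl) %% Lz
      })
  }

  truthTab <- data.frame(
    ion = seq_len(nIon), species = plan$species, type = plan$type,
    up = as.integer(plan$type %in% c("full_up", "pbc_wrapped_cross")),
    down = as.integer(plan$type == "full_down"),
    stringsAsFactors = FALSE)

  z <- withSeed(seed, {
    m <- t(vapply(plan$type, mkPath, numeric(nFrames)))
    if (noiseSd > 0) {
      ## noise must not push a path across a boundary it should not
      ## cross; clip to a conservative amplitude
      m <- m + matrix(pmin(pmax(rnorm(length(m), 0, noiseSd), -0.1), 0.1),
                      nrow = nIon)
    }
    m %% Lz
  })
  rownames(z) <- seq_len(nIon)
  out <- list(z = z, plan = plan, truth = truthTab)
  attr(out, "groundTruth") <- list(
    generator = "synth_ion_paths", seed = seed, slab = slab, Lz = Lz,
    nFrames = nFrames, truth = truthTab)
  out
}
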