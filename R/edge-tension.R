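#' Membrane edge tension from a pressure/box series
#'
#' Estimates the edge tension of an open membrane edge from the
#' stationary anisotropy of the pressure tensor in a fixed-edge
#' simulation:
#' \deqn{\gamma = \frac{1}{n_{edges}}\left\langle L_x L_y
#'   \left[\tfrac{1}{2}(P_{xx}+P_{yy}) - P_{zz}\right]\right\rangle}
#' converted from bar nm^2 to pN (factor 0.1).  The convention is the
#' rotated-box protocol: the open edge lies along z (its length fixed),
#' the two lateral dimensions are pressure coupled, and gamma is
#' positive when Pzz is tensile relative to the lateral pressures.  The
#' standard error is computed over non-overlapping block means; with
#' fewer than 2 blocks the SEM is reported as NA and gamma is still
#' returned.  As a time average the estimate is invariant under frame
#' reordering.
#'
#' @param series a [PressureBoxSeries].
#' @param nEdges number of open edges in the simulated system (2 for a
#'   membrane strip with both edges open).
#' @param discard initial time window to drop, in ns (frames with
#'   time <= discard are removed).
#' @param blockLen block length in ns for the SEM; default is one tenth
#'   of the retained span.
#' @return an [EdgeTensionResult].
#' @examples
#' s <- new("PressureBoxSeries", time = 0:9 * 1.0,
#'          Pxx = rep(1, 10), Pyy = rep(1, 10), Pzz = rep(-3.32, 10),
#'          Lx = rep(20, 10), Ly = rep(20, 10))
#' tension(edgeTension(s))  # 86.4 pN
#' @export
edgeTension <- function(series, nEdges = 2L, discard = 0,
                        blockLen = NULL) {
  stopifnot(is(series, "PressureBoxSeries"), nEdges >= 1)
  keep <- if (discard > 0) series@time > discard else
    rep(TRUE, length(series@time))
  n <- sum(keep)
  if (n < 1L)
    stop("no frames retained after discarding the first ", discard, " ns")
  g <- (series@Lx[keep] * series@Ly[keep] *
          ((series@Pxx[keep] + series@Pyy[keep]) / 2 -
             series@Pzz[keep])) * BAR_NM2_TO_PN / nEdges
  gamma <- mean(g)
  tt <- series@time[keep]
  span <- if (n > 1L) max(tt) - min(tt) else 0
  if (is.null(blockLen)) blockLen <- span / 10
  framesPerBlock <- if (blockLen > 0 && span > 0)
    max(1L, floor(n * blockLen / span)) else n
  nBlocks <- n %/% framesPerBlock
  if (nBlocks >= 2L) {
    ord <- order(tt)
    gb <- g[ord][seq_len(nBlocks * framesPerBlock)]
    blockMeans <- colMeans(matrix(gb, nrow = framesPerBlock))
    sem <- sd(blockMeans) / sqrt(nBlocks)
  } else {
    sem <- NA_real_
    nBlocks <- max(nBlocks, 0L)
  }
  new("EdgeTensionResult", gamma = gamma, sem = sem,
      nEdges = as.integer(nEdges), nBlocks = as.integer(nBlocks),
      discarded = as.numeric(discard))
}

#' Keep only the last part of a pressure/box series
#'
#' Retains frames with `time > total - keepLast`, the standard
#' discard-the-equilibration windowing (e.g. keep the last 500 ns of a
#' 530 ns run).
#'
#' @param series a [PressureBoxSeries].
#' @param total total simulated time in ns (default: max time in the
#'   series).
#' @param keepLast window length to retain, in ns (<= total).
#' @return a [PressureBoxSeries] restricted to the retained window.
#' @export
retainedWindow <- function(series, keepLast, total = NULL) {
  stopifnot(is(series, "PressureBoxSeries"))
  if (is.null(total)) total <- max(series@time)
  stopifnot(keepLast <= total)
  ## strict ">" up to a tolerance so keepLast == total is the identity
  keep <- series@time > total - keepLast - 1e-9
  new("PressureBoxSeries", time = series@time[keep],
      Pxx = series@Pxx[keep], Pyy = series@Pyy[keep],
      Pzz = series@Pzz[keep], Lx = series@Lx[keep], Ly = series@Ly[keep])
}

#' Free-energy change of shortening a membrane edge
#'
#' The free energy released by shortening an open edge of tension
#' `gamma` by `deltaLen`: `dF = gamma * deltaLen`, reported in J and in
#' units of kB*T at the given temperature.
#'
#' @param gamma edge tension in pN.
#' @param deltaLen edge length change in nm.
#' @param temperature temperature in K for the kB*T conversion.
#' @return list(joule, kBT).
#' @examples
#' edgeFreeEnergy(86.4, 1, 298.15)$kBT  # ~20.99, rounds to 21
#' @export
edgeFreeEnergy <- function(gamma, deltaLen, temperature = 310.15) {
  stopifnot(temperature > 0)
  dF <- gamma * deltaLen * PN_NM_TO_J
  list(joule = dF, kBT = dF / (kBoltzmann * temperature))
}

#' Vesiculation stability criterion for a circular membrane patch
#'
#' A circular patch of diameter D becomes mechanically unstable against
#' closing into a vesicle when its edge energy exceeds its bending
#' energy, `pi * D * gamma = 8 * pi * kappa`.  `vesiculationThreshold`
#' returns the largest bending rigidity at which a patch of diameter
#' `diameter` is unstable, `kappa_max = D * gamma / 8`;
#' `criticalDiameter` inverts the relation, `Dc = 8 * kappa / gamma`.
#'
#' @param diameter patch diameter in nm.
#' @param gamma edge tension in pN.
#' @param kappa bending rigidity in pN nm.
#' @param temperature temperature in K for the kBT conversion.
#' @return `vesiculationThreshold`: list(pNnm, kBT);
#'   `criticalDiameter`: diameter in nm (Inf when gamma is 0, with a
#'   warning).
#' @export
vesiculationThreshold <- function(diameter, gamma, temperature = 310.15) {
  stopifnot(diameter > 0, gamma >= 0)
  kmax <- diameter * gamma / 8
  list(pNnm = kmax, kBT = kmax / kBTpnnm(temperature))
}

#' @rdname vesiculationThreshold
#' @export
criticalDiameter <- function(kappa, gamma) {
  stopifnot(kappa > 0, gamma >= 0)
  if (gamma == 0) {
    warning("gamma = 0: critical diameter is infinite")
    return(Inf)
  }
  8 * kappa / gamma
}

#' Read a pressure/box series from TSV
#'
#' Expected columns: time_ns, Pxx_bar, Pyy_bar, Pzz_bar, Lx_nm, Ly_nm.
#' Lines starting with `#` are comments.  (GROMACS energy exports can be
#' converted to this layout with `gmx energy` followed by column
#' renaming; no binary reader is provided.)
#'
#' @param path TSV file path.
#' @return a [PressureBoxSeries].
#' @export
readPressureSeries <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("time_ns", "Pxx_bar", "Pyy_bar", "Pzz_bar", "Lx_nm", "Ly_nm")
  if (!all(need %in% names(df)))
    stop("pressure series must have columns: ",
         paste(need, collapse = ", "))
  new("PressureBoxSeries", time = df$time_ns, Pxx = df$Pxx_bar,
      Pyy = df$Pyy_bar, Pzz = df$Pzz_bar, Lx = df$Lx_nm, Ly = df$Ly_nm)
}

#' Write a pressure/box series to TSV
#'
#' @param series a [PressureBoxSeries].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePressureSeries <- function(series, path) {
  df <- data.frame(time_ns = series@time, Pxx_bar = series@Pxx,
                   Pyy_bar = series@Pyy, Pzz_bar = series@Pzz,
                   Lx_nm = series@Lx, Ly_nm = series@Ly)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# poremetrics pressure/box series (bar, nm, ns)", con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
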