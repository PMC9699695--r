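## Centralized unit conversions and physical constants.
## Internal units: nm, ns, bar, pN; energies in J or kBT.

#' Physical constants and unit conversions
#'
#' `kBoltzmann` is in J/K.  `BAR_NM2_TO_PN` converts bar*nm^2 to pN
#' (1 bar = 1e5 Pa; 1 Pa*nm^2 = 1e-6 pN, hence 0.1).  `PN_NM_TO_J`
#' converts pN*nm to J.
#'
#' @name constants
#' @keywords internal
NULL

kBoltzmann <- 1.380649e-23
BAR_NM2_TO_PN <- 0.1
PN_NM_TO_J <- 1e-21
ANGSTROM_TO_NM <- 0.1

#' Thermal energy in pN nm
#'
#' @param temperature temperature in K.
#' @return kB*T expressed in pN nm.
#' @examples
#' kBTpnnm(298.15)  # ~4.116 pN nm
#' @export
kBTpnnm <- function(temperature) {
  stopifnot(temperature > 0)
  kBoltzmann * temperature / PN_NM_TO_J
}

## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards.  All generators funnel through
## this so no hidden global state leaks between calls.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

## Minimum-image displacement components for an orthorhombic box.
minImage <- function(d, boxLen) d - boxLen * round(d / boxLen)

## FNV-1a hash over serialized R objects; used only to stamp run reports.
fnv1aHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    ## xor touches only the low byte (b < 256); h itself exceeds int range
    lowByte <- h %% 256
    h <- h - lowByte + bitwXor(as.integer(lowByte), b)
    ## 32-bit multiply by the FNV prime, split to stay inside double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
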