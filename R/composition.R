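#' Asymmetric plasma-membrane mimetic recipe
#'
#' Mole-percent composition and formal headgroup charges of an
#' asymmetric plasma-membrane mimetic: a cholesterol-rich outer leaflet
#' dominated by PC and sphingomyelin species, and an inner leaflet rich
#' in PE, PS and PI(4,5)P2 (charge -4).  Inner-leaflet percentages sum
#' to 99.9 (a printed rounding artifact); [planLeaflet()] normalizes
#' before apportioning.
#'
#' @return data.frame with columns `species`, `charge`, `inner`,
#'   `outer` (mole percent).
#' @export
plasmaMembraneRecipe <- function() {
  data.frame(
    species = c("CHOL", "PSM", "NSM", "LSM", "PLPC", "SOPC", "PAPC",
                "POPC", "DPPC", "PLA20PE", "PDoPE", "SAPE", "POPE",
                "PAPS", "SAPS", "PIP2"),
    charge = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, -1, -1, -4),
    inner = c(40.4, 1.0, 0, 0, 8.1, 0, 0, 3.0, 2.0, 11.1, 8.1, 4.0,
              3.0, 13.1, 1.0, 5.1),
    outer = c(40.0, 12.0, 9.0, 8.0, 15.0, 7.0, 5.0, 0, 0, 3.0, 0, 0,
              0, 0, 1.0, 0),
    stringsAsFactors = FALSE)
}

#' Integer leaflet composition by largest-remainder apportionment
#'
#' Converts a mole-percent recipe into integer lipid counts for a
#' leaflet of `nLipids` lipids.  Percents are normalized to sum to 100,
#' quotas `pct * n / 100` are floored (with a 1e-9 tolerance against
#' floating-point quota representation), and the remaining lipids go to
#' the largest fractional remainders, ties broken by recipe order.
#' Every species then satisfies the quota property
#' `|count/n - pct/100| <= 1/n`.
#'
#' @param recipe data.frame with columns `species`, `charge` and a
#'   mole-percent column named by `leaflet`.
#' @param nLipids leaflet size (>= 1).
#' @param leaflet which percent column to use ("inner" or "outer").
#' @return data.frame with columns `species`, `charge`, `percent`
#'   (normalized), `count`; attribute `nTotal`.  Species with positive
#'   percent but zero count are allowed (and noted via message).
#' @export
planLeaflet <- function(recipe, nLipids, leaflet = "inner") {
  stopifnot(nLipids >= 1, leaflet %in% names(recipe))
  pct <- recipe[[leaflet]]
  stopifnot(all(pct >= 0))
  total <- sum(pct)
  if (total < 99 || total > 101)
    warning("recipe percentages sum to ", total,
            " (expected within [99, 101]); normalizing")
  pctN <- pct / total * 100
  quota <- pctN * nLipids / 100
  counts <- floor(quota + 1e-9)
  remainder <- quota - counts
  shortfall <- nLipids - sum(counts)
  if (shortfall > 0) {
    ord <- order(-remainder, seq_along(remainder))
    top <- ord[seq_len(shortfall)]
    counts[top] <- counts[top] + 1
  }
  dropped <- recipe$species[pct > 0 & counts == 0]
  if (length(dropped))
    message("species with nonzero percent but zero count: ",
            paste(dropped, collapse = ", "))
  out <- data.frame(species = recipe$species, charge = recipe$charge,
                    percent = pctN, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "nTotal") <- as.integer(nLipids)
  out
}

#' Net formal charge of a leaflet plan
#'
#' @param plan data.frame from [planLeaflet()] (columns `count`,
#'   `charge`).
#' @return integer net charge.
#' @export
leafletCharge <- function(plan) {
  as.integer(sum(plan$count * plan$charge))
}

#' Sodium/chloride counterion counts
#'
#' Sodium is added at the requested concentration using the water-based
#' molarity convention (moles of salt per 55.5 moles of water); the
#' neutralizing counterion is then added so the total system charge is
#' zero -- excess chloride when the net charge including sodium is
#' positive (the typical case for a positively charged protein on a
#' negative membrane), extra sodium otherwise.
#'
#' @param nWater number of water molecules (> 0).
#' @param systemNetCharge net formal charge of the solute (protein +
#'   membrane) before any ions.
#' @param concentration salt concentration in mol/L (default 0.150).
#' @return list(nNa, nCl, netCharge = 0 check value).
#' @examples
#' counterionCounts(55500, 10)  # nNa 150, nCl 160
#' @export
counterionCounts <- function(nWater, systemNetCharge,
                             concentration = 0.150) {
  stopifnot(nWater > 0)
  nNa <- round(concentration * nWater / 55.5)
  afterNa <- systemNetCharge + nNa
  if (afterNa >= 0) {
    nCl <- afterNa
  } else {
    nNa <- nNa - afterNa  # add extra sodium instead
    nCl <- 0
  }
  list(nNa = as.integer(nNa), nCl = as.integer(nCl),
       netCharge = as.integer(systemNetCharge + nNa - nCl))
}

#' Leaflet asymmetry repair after clash removal
#'
#' When inserting a protein removes different numbers of lipids from
#' the two leaflets, the introduced imbalance is repaired by removing
#' additional random lipids from the leaflet that lost fewer (the one
#' now holding the surplus), until the removal tallies match across
#' leaflets and the membrane's designed asymmetry is restored.  Sterols
#' and phospholipids are treated as separate groups: each group is
#' balanced independently, so a sterol surplus is repaired by removing
#' sterols only.  The draw is seeded and reproducible; different seeds
#' change which lipids go, never how many.
#'
#' @param innerPlan,outerPlan leaflet plans ([planLeaflet()] output or
#'   any data.frame with `species` and `count`).
#' @param removedInner,removedOuter named numeric vectors
#'   `c(phospholipid = , sterol = )` of clash-removal tallies.
#' @param sterolSpecies species names counted as sterols.
#' @param seed RNG seed.
#' @return list with per-leaflet removal instructions (`inner`,
#'   `outer`: named integer vectors species -> count to remove) and
#'   `summary` (data.frame: group, leaflet, nRemove).
#' @export
asymmetryRepair <- function(innerPlan, outerPlan,
                            removedInner = c(phospholipid = 0, sterol = 0),
                            removedOuter = c(phospholipid = 0, sterol = 0),
                            sterolSpecies = STEROL_RESNAMES,
                            seed = NULL) {
  groupOf <- function(plan) ifelse(toupper(plan$species) %in%
                                     toupper(sterolSpecies),
                                   "sterol", "phospholipid")
  `%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
  instructions <- list(inner = integer(0), outer = integer(0))
  summary <- data.frame(group = character(), leaflet = character(),
                        nRemove = integer(), stringsAsFactors = FALSE)
  withSeed(seed, {
    for (grp in c("phospholipid", "sterol")) {
      lostIn <- as.numeric(removedInner[grp] %||% 0)
      lostOut <- as.numeric(removedOuter[grp] %||% 0)
      ## the leaflet that lost fewer lipids of this group now holds the
      ## surplus; equalize the tallies by removing from it
      diff <- lostIn - lostOut
      if (diff == 0) next
      leaflet <- if (diff > 0) "outer" else "inner"
      plan <- if (diff > 0) outerPlan else innerPlan
      removed <- if (diff > 0) removedOuter else removedInner
      nRemove <- abs(diff)
      pool <- plan[groupOf(plan) == grp & plan$count > 0, , drop = FALSE]
      avail <- sum(pool$count) - as.numeric(removed[grp] %||% 0)
      if (nRemove > avail)
        stop("cannot remove ", nRemove, " ", grp, "s from the ",
             leaflet, " leaflet: only ", avail, " available")
      picks <- sample(rep(pool$species, pool$count), nRemove)
      tab <- table(picks)
      cur <- instructions[[leaflet]]
      for (spName in names(tab))
        cur[spName] <- (if (spName %in% names(cur)) cur[spName] else 0L) +
          as.integer(tab[spName])
      instructions[[leaflet]] <- cur
      summary <- rbind(summary,
                       data.frame(group = grp, leaflet = leaflet,
                                  nRemove = as.integer(nRemove),
                                  stringsAsFactors = FALSE))
    }
  })
  list(inner = instructions$inner, outer = instructions$outer,
       summary = summary)
}
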