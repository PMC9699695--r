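---
title: "Methods and design of poremetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of poremetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremetrics)
```

# Scope

poremetrics is the quantitative analysis layer for molecular-dynamics
studies of pore-forming proteins on lipid membranes, built around the
gasdermin-D N-terminal domain (GSDMD-NT) use case: a cytosolic effector
that binds the inner leaflet of the plasma membrane, oligomerizes into
arcs and rings, and opens large transmembrane pores.  The package does
not run molecular dynamics.  It consumes structures (GRO/PDB),
trajectories (concatenated GRO frames), pressure/box time series (TSV),
amino-acid sequences and leaflet recipes, and computes the observables a
pore-formation study reports: membrane edge tension, lipid-protein
contact statistics, ion permeation, pore and membrane geometry,
hydrophobicity scores, and leaflet composition plans.

Internal units are nm, ns, bar and pN (kcal/mol for hydrophobicity).
Frames are indexed 0-based and all intervals are half-open
`[start, end)`.

# Membrane edge tension

An open bilayer edge costs free energy per unit length -- the edge
tension $\gamma$.  In a fixed-edge simulation protocol the membrane
strip is rotated so the open edge runs along $z$, the box length along
$z$ is fixed, and the two lateral dimensions are pressure-coupled.  The
tension then appears as a stationary anisotropy of the pressure tensor:

$$\gamma = \frac{1}{n_\mathrm{edges}}\left\langle L_x L_y \left[
  \tfrac12 (P_{xx}+P_{yy}) - P_{zz}\right]\right\rangle,$$

with the factor $1/n_\mathrm{edges}$ (default 2) accounting for the two
open edges of a periodic strip, and a conversion factor of 0.1 from
bar nm$^2$ to pN.  `edgeTension()` implements exactly this average;
`retainedWindow()` drops the equilibration transient (e.g. keep the
last 500 ns of a 530 ns run).  The sign convention -- positive $\gamma$
when $P_{zz}$ is tensile relative to the lateral pressures -- is fixed
by the rotated-box protocol and documented on the function.

Uncertainty is estimated by non-overlapping block averaging: the
retained span is cut into blocks of `blockLen` ns and the SEM is the
standard deviation of block means over $\sqrt{n_\mathrm{blocks}}$.  The
default block length is one tenth of the retained span (at least two
blocks), a common choice when the autocorrelation time is unknown.  On
white-noise synthetic series we validate coverage with 100 blocks
instead: block means are then i.i.d., and with $\approx 100$ degrees of
freedom the $3\times$SEM interval has close to its nominal 99.7%
coverage, which is what a 99%-of-replicates check assumes.  With only
10 blocks the same check would fail for purely statistical reasons
(a $t_9$ interval at $3\hat\sigma$ covers only $\approx 98.5\%$).

Two derived quantities are provided.  `edgeFreeEnergy()` converts a
tension into the free-energy drop of shortening the edge
($\Delta F = \gamma\,\Delta\ell$, reported in J and $k_BT$).  The
default temperature is 310.15 K (a typical simulation temperature);
the textbook round number "21 kBT per nm at 86.4 pN" is reproduced at
298.15 K (20.99), and both temperatures are exposed because the
conversion temperature is a user choice, not data.
`vesiculationThreshold()`/`criticalDiameter()` implement the classical
stability relation for a circular patch, $\pi D_c \gamma = 8\pi\kappa$,
literally: $D_c = 8\kappa/\gamma$.  Note that for a 20 nm patch at
86.4 pN this relation bounds $\kappa$ at $\approx 216$ pN nm
($\approx 50\,k_BT$ at 310 K); smaller published bounds follow only if
the radius rather than the diameter is inserted, so the function
implements the printed relation and leaves interpretation to the user.

# Lipid-protein contacts

Contacts are defined on heavy atoms only: a lipid contacts a protein
residue in a frame when the minimum distance between the lipid's
headgroup heavy atoms and the residue's heavy atoms is at or below
0.36 nm (strict $\le$).  Distances honor the minimum-image convention
in all three directions; boxes smaller than twice the cutoff are
rejected.  The search uses a cell list (linear scaling), and the test
suite verifies exact agreement with an all-pairs brute force on every
fixture, including boxes barely above the minimum-image limit.

Residence times use the dual-cutoff scheme: an interval opens when the
pair distance drops to 0.36 nm and closes only when it exceeds
0.50 nm.  This suppresses "rattling-in-a-cage" artifacts where a bound
lipid briefly vibrates past the tight cutoff without actually leaving.
Setting both cutoffs equal recovers plain single-cutoff segmentation.
Intervals separated by even a single frame above the release cutoff
are *not* merged -- a deliberate, reproducible rule.  Two analysis
windows are exposed because they serve different purposes: occupancy
and enrichment are computed after discarding an initial window
(default 500 ns), while duration counting may run on full trajectories.

Enrichment compares a lipid species' share of contact records with its
mole fraction in the reference leaflet (inner by default, the leaflet
a cytosolic pore-former binds): enrichment 1 means "as often as
abundance predicts".  Species in contact but absent from the leaflet
census give an undefined (NA) enrichment, reported as such.

A *bridging lipid* simultaneously contacts two adjacent subunits of an
oligomer -- double-sided tape across an interface.  Adjacency is
restricted to consecutive subunits along the arc (closed into a ring on
request); lipids contacting two non-adjacent subunits are tallied
separately rather than silently counted, since interface bridging is
the mechanistically interesting configuration.  Whether bridging should
count whole-lipid atoms or headgroup atoms is not fixed by convention;
the default is headgroup heavy atoms, consistent with the contact
definition above.

# Ion permeation and water continuity

Permeation is counted by complete slab traversals.  The membrane slab
is bounded by the per-leaflet mean headgroup-phosphate heights (fixed
over the analysis window rather than per frame, so membrane undulation
cannot generate spurious events).  A three-state machine per ion
(below / inside / above) records an event only when the ion enters the
slab from one side and exits the other; re-entries from the same side
count nothing, so an ion dithering across one boundary fifty times
contributes zero events.  The wrapped $z$ series is unwrapped first
(jump threshold $L_z/2$), so a traversal whose tail wraps through the
periodic box edge is counted exactly once.  The test suite checks every
path type (full crossings both ways, rebounds, boundary dither,
periodic wrapping) against a brute-force state-sequence oracle.

Water-column continuity asks whether a pore holds an unbroken water
file: the slab is cut into bins of 0.3 nm (about one water diameter)
and the column is continuous when every bin contains at least one
water oxygen within the pore cylinder.  A zero-radius cylinder is
degenerate (never continuous) and warned about.

# Pore and membrane geometry

*Pore radius.* Lipid heavy atoms within 1 nm of the membrane midplane
are rasterized onto a 0.5 nm $(x,y)$ grid; the empty region reachable
from the analysis center (protein centroid, else patch center) is
found by flood fill, and the pore radius is the largest disc centered
there inside the empty region.  The disc radius itself is refined
against the actual atom positions (the region boundary), which removes
raster noise when cells are sparsely occupied.  Pores smaller than
max(grid, 1 nm) are reported as "no pore", as is an occupied center
cell.  The published magnitude this emulates is a pore about 21.6 nm
wide; whether that width is lipid-edge-to-lipid-edge or
protein-defined is not standardized, and this implementation measures
the lipid-free region.

*Crown deformation.* Prepore rings bend the enclosed membrane upward
into a crown.  The profile is the radial binning of headgroup heights
about the ring center; the far-field reference is the mean over the
outermost 20% of radii, and the crown height is the profile apex minus
that reference.  Because the apex sits on the axis where bins hold few
lipids, the apex is estimated by linear extrapolation of the two
innermost valid bins to $r = 0$ using each bin's actual mean radius --
exact for a locally linear profile, and a small-noise correction
otherwise.  The synthetic generator plants a linear crown profile
(height decaying linearly to the ring radius); the real deformation
shape is not parameterized by any published form, so the linear shape
is a generator choice recorded in its ground truth.

*Hairpin tilt.* The angle between a subunit's base-to-tip hairpin
vector and the membrane plane ($90^\circ$ = membrane normal, $0^\circ$
= in-plane), reported per subunit.  Emulated magnitudes: transmembrane
hairpins tilting to $\approx 55^\circ$ at curled sheet edges, and
$\approx 30^\circ$ amphipathic helix tilts.

*Ring circularity and cracks.* Subunit globular-domain centroids are
fit with the algebraic (Kasa) circle fit -- closed-form, deterministic,
zero residual for exact circles.  Arc cracking under membrane edge
tension is detected from per-interface inter-subunit heavy-atom
contact counts: an interface is cracked at the first frame where its
count stays below 5 contacts for at least 50 consecutive frames.  Both
numbers are configurable because published crack times come without a
stated criterion; a persistence window is essential to avoid
classifying a single fluctuation as a crack, and a zero threshold
degenerates to "never cracks".

*Membrane thinning.* Per $(x,y)$ bin, the difference between mean
upper- and lower-leaflet phosphate heights; bins missing either
leaflet are NA rather than zero, and the bulk reference is the median
over valid bins.

# Hydrophobicity scoring

Pore-facing residue stretches are scored by summing per-residue values
of the Eisenberg consensus hydrophobicity scale (kcal/mol).  Several
variants of that scale circulate in the literature; the shipped table
is the variant that reproduces the published two-decimal per-strand
sums for both gasdermin beta barrels, and any other variant can be
supplied as a two-column TSV.  The score is additive and
permutation-invariant (it is a sum), the empty sequence scores zero,
and unknown letters are an error naming the offending position.
`hydrophilicityExcess()` compares two (negative) sheet totals as a
percentage of magnitudes.

# Membrane composition planning

Mole-percent recipes are converted into integer per-leaflet counts by
largest-remainder (Hamilton) apportionment: normalize percents to 100,
floor the quotas, and hand the remaining lipids to the largest
fractional remainders (ties by recipe order).  This method satisfies
the quota property $|c_s/n - p_s/100| \le 1/n$ and reproduces the
asymmetric plasma-membrane census used throughout (99 inner / 100
outer lipids, including 5 PI(4,5)P2 at $-4$ and 14 PS at $-1$, net
inner charge $-34$).  Quotas are floored with a $10^{-9}$ tolerance:
the quota $11.1 \times 99 / 99.9$ is exactly 11 in real arithmetic but
$10.999\ldots$ in doubles, and the tolerance makes the floor
deterministic (the final allocation is the same either way, through
the remainder ranking).  The inner-leaflet percents as printed sum to
99.9, a rounding artifact; normalization precedes apportionment.

Counterions follow the "salt then neutralize" rule: sodium at 150 mM
using the water-based molarity convention (moles per 55.5 moles of
water -- switchable in principle to box-volume molarity, but the
water-count convention is the one that reproduces round ion numbers),
then the neutralizing species (chloride for net-positive systems,
extra sodium otherwise) to exact charge zero.

Protein insertion removes clashing lipids unevenly from the two
leaflets.  `asymmetryRepair()` restores the *designed* asymmetry by
removing additional random lipids from the leaflet that lost fewer,
until removal tallies match per group.  Sterols and phospholipids are
balanced independently -- cholesterol flip-flops on its own and its
leaflet balance is a separate equilibrium -- so a sterol surplus is
never repaired by deleting phospholipids.  The draw is seeded; seeds
change which lipids are picked, never how many.

# Synthetic systems and what they do (not) show

Every analysis stage has a seeded generator producing its input class
with recorded ground truth (`groundTruth()`); identical seeds give
byte-identical fixtures and generators restore the caller's RNG state.
The generators are deliberately minimal: lipids are one headgroup bead
plus one midplane tail bead, subunits are bead clusters with two-bead
hairpins, ions are one-dimensional $z$ paths.  This is sufficient
because the analysis operators consume exactly these observables
(headgroup positions, heavy-atom distances, $z$ series), and it keeps
the full validation suite at desk scale.

Defaults encode the emulated study conditions: a 99/100-lipid
asymmetric patch at $\approx$0.65 nm$^2$ per phospholipid, leaflet
separation 4 nm, contact cutoffs 3.6/5 A, 500 ns discard windows,
two open edges, 150 mM salt, a 10.8 nm planted pore radius (21.6 nm
diameter), 55$^\circ$ hairpin tilts, a 16-mer arc cracking at
interface (8,9) at 0.89 us.  Problem sizes in the tests were chosen
as the smallest that leave the statistical checks well-powered:
50,000-frame pressure series across 200 seeds for estimator coverage,
50 random frames for the cell-list/brute-force identity,
1,000-3,000-lipid patches for geometry recovery.

What passing these tests does *not* show: the generators have no
lipid chemistry, no protein flexibility, no correlated noise (pressure
series are white, so block-averaging validation at short blocks says
nothing about autocorrelated real data -- use longer blocks there), no
membrane undulations beyond the planted deformations, and flat
leaflets otherwise.  Conclusions about real trajectories still require
the real trajectories.

# Numerical choices and degenerate inputs

* Contact cutoffs are strict $\le$; the boundary case 0.36 nm is a
  contact, 0.37 nm is not.
* `retainedWindow()` keeps times strictly greater than
  `total - keepLast` with a $10^{-9}$ ns tolerance, so
  `keepLast = total` is the identity and `keepLast = 0` empties the
  series (tripping the estimator's precondition).
* Fewer than 2 SEM blocks: $\gamma$ is still returned, SEM is NA.
* Leaflet assignment warns and labels everything "outer" when the
  lipid reference atoms span less than 1 nm in $z$ (a single sheet);
  crowns lower than half the leaflet separation do not flip labels
  because the midplane is global.  The headgroup reference atom
  defaults to phosphorus (hydroxyl oxygen for sterols) and is
  configurable, since no convention fixes which atom "is" the lipid.
* Element inference uses the first alphabetic character of the atom
  name with an ion/bead exception table; GRO carries no element field.
* Empty enrichment denominators, empty leaflets, sub-3-subunit circle
  fits, non-finite ion coordinates, and atom-count changes mid
  trajectory are all hard errors naming the offending entity.

# Command-line interface

`inst/scripts/poremetrics` is a thin Rscript front end (subcommands
`synth`, `edge-tension`, `contacts`, `permeation`, `geometry`,
`hydrophobicity`, `plan-membrane`, `run`) over the exported functions;
`runPipeline()` executes multi-stage configs (flat YAML key-value
blocks, flags overriding config) and stamps every report with a config
hash and seed so identical configs reproduce identical numbers.

# Known limitations

* Orthorhombic boxes only; no triclinic minimum image.
* No topology/bond parsing, no binary trajectory formats (PSF, TPR,
  XTC); the concatenated-GRO dialect is the reference interchange.
* Pore radius assumes a single, roughly centered pore; multiple pores
  report only the centered one.
* Boundaries for permeation are planar; strongly curved membranes
  would need curved slab definitions.
* The crack detector consumes contact-count series; computing those
  series over long trajectories is the caller's loop
  (`subunitContactCounts()` per frame).
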