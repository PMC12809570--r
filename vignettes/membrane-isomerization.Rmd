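---
title: "Comparing all-cis and all-trans bilayers: models, metrics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing all-cis and all-trans bilayers: models, metrics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memiso)
```

## The scientific problem

Several *Pseudomonas* species respond to membrane stress by enzymatically
isomerizing the cis double bonds of their phospholipid acyl tails to trans
(the cis–trans isomerase, Cti, acts within minutes, long before new lipid
synthesis can help).  A trans double bond leaves the chain nearly straight;
a cis bond kinks it.  At the membrane scale this single stereochemical
change alters thickness, in-plane packing, chain order, lateral mobility,
and — the most mechanistically interesting part — how often the double bond
itself visits the headgroup region where a peripheral enzyme could reach it.

`memiso` implements the complete analysis pipeline for quantifying these
differences between all-cis and all-trans bilayer trajectories of a
*P. putida* inner-membrane model: a 100-lipid, two-leaflet patch mixing PE
and PG glycerophospholipids with cardiolipin (per-leaflet counts
PYPE 10, POPE 7, YOPE 14, PYPG 11, POPG 6, PVCL2 2; all unsaturations
Delta-9).  It also provides the geometric cis→trans conversion operator used
to build the trans condition from a cis membrane, and a synthetic
bilayer-trajectory generator whose every statistical property is known in
closed form, so that each metric can be validated by parameter recovery
rather than by eye.

## Metrics

All coordinates are ångström, times nanoseconds; the bilayer normal is the
z axis; boxes are orthorhombic with xy periodicity (z is treated
non-periodically — the membrane is centred by construction).

**Thickness and volume.** Thickness is the difference between the mean z of
the upper leaflet's phosphate atoms and the lower leaflet's, per frame.
Volume multiplies the in-plane box area by that thickness.  Both are
reported per frame and averaged per replicate.

**Leaflet assignment** uses the sign of each residue's phosphate-centroid z
relative to the global phosphate mean.  Residues within 5 Å of the midplane
(never the case in these systems) are resolved by tail direction and
flagged.

**Area per lipid (APL)** partitions the membrane plane with a grid of at
most 1 Å spacing laid at ±18 Å from the phosphate midplane (both
configurable), assigning each grid point to the nearest lipid residue of
that side's leaflet — heavy atoms only, 3D distance with xy minimum image
(a 2D mode is available).  Per-type area is assigned cells × cell area ÷
type count.  Because every cell is assigned exactly once, total area is
conserved exactly; the compiled nearest-neighbour scan is tested
cell-for-cell against a brute-force distance-matrix oracle in R.
Restricting candidates to one leaflet prevents the opposing leaflet from
capturing cells; ties break toward the earlier atom in file order.

**Chain order.** `sch()` computes S_CH = ⟨3 cos²θ − 1⟩/2 per tail carbon,
with θ between each explicit C–H bond vector and the z axis, averaged over
hydrogens, residues and frames.  Explicit hydrogens are required — the
model system is all-atom and the generator emits them; reconstructing
hydrogens from heavy atoms would add untestable conventions.  The normal is
fixed to z (the convention of the membrane plug-in tools this reproduces),
and the signed value is reported, not |S_CD|.  `order_timeseries()` windows
the tail mean over time to expose order drift such as a phase change.

**Kink angle** is the interior angle at the unsaturation (the
glycerol-proximal carbon of the C=C bond) between vectors to the tail's
terminal and carbonyl carbons.  For multiply unsaturated tails the first
site would be used; cardiolipin's four tails are measured independently.

**Double-bond depth and surface accessibility.** Per frame and leaflet the
reference plane is the mean z of that leaflet's phosphorus atoms (the
measured phosphate *distribution*, by contrast, includes the phosphate
oxygens).  The signed depth d is positive toward the midplane, negative
past the plane into water.  `surface_fraction()` reports the fraction of
double-bond-carbon samples with d ≤ 5 Å — the water side counts, because
excursions past the plane are precisely the phenomenon of interest (an
absolute-window rule is a switch).  Samples are per-atom (two carbons per
bond), switchable in principle by subsetting the selection.

**Lateral diffusion.** Residue positions are heavy-atom centroids (the
least arbitrary reading of "lipid residue"); tracks are unwrapped across
the xy boundary, drift-corrected per leaflet (subtracting each frame's
leaflet-mean centroid so collective sliding does not masquerade as
diffusion) and split into non-overlapping chunks that each restart the
reference position x₀.  MSD(t) = ⟨|r_xy(t) − r_xy(t₀)|²⟩ uses a single time
origin per chunk by default (a multi-origin mode exists).  The diffusion
coefficient applies D = MSD(T)/(2·n·T) with n = 2 literally to each chunk's
endpoint — reproducing the estimator's arithmetic exactly — while a
least-squares line through the origin is offered as the better estimator
(the two agree exactly on perfectly linear MSD).  The estimate per lipid
type is the mean over chunk × replicate samples with SE = sd/√n, so 5
replicates × 5 chunks gives n = 25.  Units: 1 Å²/ns = 1 × 10⁻⁷ cm²/s.
Cardiolipin is one residue, hence one track, despite four tails.

## The isomerization operator

`isomerize_site()` rotates everything distal to a C=C bond (toward the
chain terminus) by 180° about the axis through the two double-bond carbons,
found by deleting that bond from the bond graph and taking the terminal
component (a ring would be refused).  The operation is a pure rigid
rotation: an exact isometry on the rotated set and an involution to well
below 10⁻⁶ Å.  Classification calls a site cis iff its |torsion| < 90°,
with 90° itself — the symmetry point, since the source protocol names no
threshold — classed trans.  The rotated structures are not re-minimized;
the operator is purely geometric, mirroring how the trans membranes were
prepared from built cis membranes.

## The synthetic generator

`synthetic_spec()` + `simulate_trajectory()` produce bead-resolution
bilayers with the full model composition: balanced phosphate bead sets
(each residue's phosphate centroid sits exactly on its leaflet plane, so
built thickness is exact), planar zig-zag acyl chains, and per-frame
resampled hydrogens.  No force field or sterics are involved — every metric
here depends only on labelled coordinates, so statistical realism is the
design target, not energetic realism.

Chain geometry is built from bond-direction angles: the first arm descends
at an 8° tilt; the double-bond C(p)–C(p+1) bond is laid exactly horizontal
(both carbons share one z, which keeps the per-atom depth law exact); the
next bond rises for cis and falls for trans, which fixes the planar torsion
to exactly 0°/180°; and the second arm's mean axis is solved by `uniroot`
so the measured kink angle equals the requested value exactly.  The
per-frame dynamics are:

* **Lateral motion** — one Brownian step per residue per frame with that
  type's D, applied rigidly and wrapped by residue.  Centroid MSD slope is
  exactly 4D in expectation because hydrogens are excluded from centroids
  and all other updates touch only z.
* **Thickness breathing** — per-frame Gaussian thickness, applied as
  opposite rigid z shifts of the leaflets.
* **Double-bond depth** — a two-state (bulk/surface) Markov chain per site,
  initialized from its stationary distribution so the pooled fraction is
  unbiased: bulk depth ~ N(μ_d, σ_d), surface excursions uniform in
  (0, 5] Å, stationary surface probability p_s, switching rate ρ (default
  0.2, i.e. sticky states with realistic autocorrelation).  The offset
  translates the rigid sub-chain from C(p−1) to the terminus, so the site
  torsion — hence cis/trans classification — is exactly invariant under the
  depth dynamics.  The closed-form expected surface fraction is
  p_s + (1 − p_s)·Φ((cutoff − μ_d)/σ_d).
* **C–H orientation** — every hydrogen resampled from the tilt law each
  frame: fixed polar angle θ₀ (S_CH = P₂(cos θ₀) exactly; θ₀ may be a
  per-frame schedule to create order steps) or isotropic (S_CH = 0).

### Default study conditions

Defaults emulate the comparison system at desk scale and are not tuned per
run:

| parameter | cis | trans | why |
|---|---|---|---|
| box (Å) | 57.0² × 80 | 55.6² × 80 | trans packs tighter (lower APL); with the thickness pair this makes the all-cis membrane ~2.5% larger in volume, the study's headline packing number |
| thickness μ, σ (Å) | 39, 0.3 | 40, 0.3 | trans thicker by ~1 Å |
| D phospholipid (Å²/ns) | 0.65 | 0.52 | 6.5 vs 5.2 × 10⁻⁸ cm²/s, the reported ranges |
| D cardiolipin (Å²/ns) | 0.30 | 0.24 | cardiolipin diffuses markedly slower |
| tilt θ₀ (deg) → S_CH | 48.8 → 0.151 | 45 → 0.25 | trans more ordered |
| depth μ_d, σ_d (Å) | 12, 2 | 13, 1.5 | double bonds buried ~1 Å deeper in trans |
| surface p_s | 0.0078 | 0.0015 | expected fractions ≈ 0.80% / 0.15%, the observed accessibility contrast |
| kink angle (deg) | 135 | 150 | ~15° more bent for cis |
| frames × dt | 501 × 0.1 ns | same | 50 ns at desk scale |

Replicate seeds are derived from the base seed by a large LCG stride rather
than consecutively: Mersenne–Twister streams started from adjacent seeds
are not independent, which would correlate "independent" replicates and
silently invalidate the chunked standard errors.

### What the generator does and does not emulate

It reproduces the *statistical structure* the metrics measure — thickness
fluctuations, per-type Brownian mobility, order via the C–H tilt law, depth
mixtures with rare excursions, exact cis/trans torsions and kink angles —
with known ground truth for each.  It does **not** model packing
correlations, anomalous (sub-diffusive) short-time lipid motion,
director tilt coupling between neighbouring chains, undulations, gel-phase
transitions, or water.  Passing the recovery battery therefore shows the
*estimators* are correct and unbiased under known conditions; it does not
by itself validate conclusions about any particular force field or real
membrane.

## Numerical choices and degenerate inputs

* cis/trans threshold |torsion| = 90°, boundary → trans; degenerate
  (collinear) torsions are an error, as is a ring reaching back across a
  rotated bond.
* APL grid: nx = ⌈Lx/s⌉ points at cell centres, actual spacing Lx/nx ≤ s;
  nearest-atom ties break toward the earlier atom (deterministic).
* Depth histograms default to 0.5 Å bins over [−10, 30] Å — fine enough to
  resolve sub-2 Å shifts of the distribution peak; out-of-range samples
  land in the end bins so densities always sum to 1.
* Unwrapping assumes per-frame displacements under half a box; a violation
  after unwrapping warns about aliasing.
* An empty leaflet, an empty depth selection, a saturated tail asked for a
  kink, or an analysis window longer than the trajectory are errors, not
  silent zeros; an APL type absent from a leaflet is reported absent.
* Trajectory frame times, if the format stores none, are synthesized as
  frame index × dt (default 10 ps, the trajectory write interval of the
  study protocol).  Coordinates are never unwrapped at read time —
  unwrapping is an explicit geometry operation because metrics disagree
  about wanting it.

## Problem sizes used in the shipped checks

The test suite validates estimator correctness at reduced scale (an
18-lipid patch for unit tests) and runs the full study-shaped battery —
100 lipids, 5 + 5 replicates, 500 frames each, every metric — in its
acceptance tests; `scripts/acceptance.R` repeats that battery from a
command-line seed and writes the aggregated numbers as JSON.  These sizes
were chosen so the whole battery completes in about a minute while leaving
every standard error small relative to its acceptance band.

## Known limitations

* XTC trajectories are not read (no XDR decoder among the package's
  dependencies); use DCD, or convert externally.  PDB/GRO structures and
  DCD trajectories are supported, and DCD writing is verified against an
  independent reader.
* The PDB writer/reader respects the 4-character residue- and atom-name
  fields; the five-character cardiolipin code PVCL2 is recovered from its
  truncation by unique prefix match against the lipid-definition table.
* The generator supports at most one unsaturation per tail (all species in
  the shipped table are Δ9 mono-unsaturated); the *analysis* side handles
  multiple sites per tail.
* Triclinic boxes are out of scope throughout; orthorhombic only.
* No statistical hypothesis tests between conditions are produced — the
  comparison report gives means, differences and replicate spreads.
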