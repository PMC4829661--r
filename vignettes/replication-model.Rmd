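---
title: "Modelling whole-genome replication kinetics and nuclear replication foci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-genome replication kinetics and nuclear replication foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliconsim)
```

## The model

repliconsim simulates S-phase of a human (HeLa-like) cell as a
one-dimensional stochastic process on a chromatin-annotated genome, and
maps the resulting replication-fork dynamics onto a polymer model of
nuclear chromatin to render in-silico microscopy images of replication
foci.

The genome is a string of ~10 Gbp partitioned into chromosomes by
*barriers* that replication forks cannot cross and across which no firing
signal propagates.  Each chromosome is tiled by chromatin zones of three
classes: euchromatin (EU), facultative heterochromatin (FAC) and
constitutive heterochromatin (CON).  Zones differ **only** in how easily
origins inside them fire at the start; forks travel freely across zone
boundaries.

Replication initiates at *potential origins* placed uniformly at random
(500,000 by default, one per ~21 kbp).  An unfired, unreplicated origin
fires with a relative probability that is the maximum of

* a **spontaneous** term, fixed per chromatin class
  (`p_eu = 0.8`, `p_fac = 0.05`, `p_con = 0`), and
* an **induced** ("domino") term contributed by nearby active forks: a
  Gaussian of the fork distance with `sigma = 240` kbp, set to zero below
  a probability cutoff of 0.1 (limiting its reach to ~515 kbp) and set to
  zero outright within the *inhibition distance* `d_i = 55` kbp of any
  active fork — no origin fires inside a replication-related chromatin
  loop that is already being replicated.

Firing creates a bidirectional fork pair.  All forks share a global speed
`v(t) = nu * min(t / ramp, 1)` with `nu = 28` bp/s and `ramp = 2.8` h: the
linear ramp from zero reproduces the two-fold lower global synthesis rate
observed in early S-phase.  Opposing forks annihilate where they meet;
a fork reaching a chromosome barrier is absorbed.

A diffusible **limiting factor** caps concurrency: each active fork holds
one unit of a pool that grows as `L(t) = L_max (1 - exp(-t / tau))`
(`L_max = 12000`, `tau = 15` min) and is returned on fork termination
(two units per collision, one per barrier absorption).  Firing consumes
two units, so at most `floor(L(t))` forks are ever active.

## The event-driven engine

The simulation is exact (no time discretization).  Because every fork
moves at the same global speed, a right-moving fork keeps a constant
anchor `u = x - s(t)` and a left-moving fork `w = x + s(t)`, where
`s(t)` is the integrated fork travel.  Ordered sets keyed on these
anchors give `O(log n)` nearest-fork queries at any time with no position
updates, and collision/barrier/zone-crossing times are closed-form
inversions of `s`.  A binary heap orders events by `(time, kind,
position)` with kind priority collision < barrier < zone crossing <
factor release; events whose forks have since died are discarded when
popped.  Collision events are only ever scheduled between adjacent
approaching partners, and a firing between such a pair always annihilates
both before the stale event surfaces, so liveness of both forks is a
sufficient validity check.

Whenever at least two factor units are free (after a collision, barrier
absorption or factor release) the engine runs a firing round: candidates
are drawn uniformly **without replacement**; a candidate found passively
replicated is discarded lazily; otherwise its probability is evaluated at
the current fork configuration and a uniform draw decides.  The round
ends when fewer than two units are free or every candidate has been
offered once.  Ending rounds after one pass (rather than repeating
indefinitely) guarantees termination when no candidate has positive
probability; firing is re-attempted at every subsequent event, so the
delay this introduces is at most one inter-event interval.  Factor
releases are scheduled at the exact times where `floor(L(t))` increments,
`t_k = -tau * log(1 - k / L_max)`; the final increment, unreachable in
exact arithmetic, is granted where `L(t) = L_max - 1/2`.

Replicated DNA is integrated exactly between events (`dR = n_forks *
ds`), attributed per class through zone-crossing bookkeeping events that
never influence dynamics.

Model variants: `spontaneous_only` disables the induced term;
`induced_only` disables the spontaneous term and instead fires one origin
per euchromatic zone at `t = 0` (a random potential origin inside the
zone, or its midpoint when it contains none).  These initial firings
bypass the limiting factor — the factor pool is empty at `t = 0` — so the
factor-accounting invariant is stated for the other variants.

## The synthetic genome

The package is self-contained: `generate_synthetic_genome()` emulates the
aneuploid HeLa karyotype used throughout — 76 chromosomes, ~10.36 Gbp,
class fractions 42/22/36% (EU/FAC/CON).  Chromosome lengths are lognormal
(shape 0.45), rescaled to the target total.  Zone sizes are lognormal
with median 2.7 Mbp and shape 0.55, placing ~80% of the genomic mass in
1–6 Mbp zones and yielding ~3,300 zones; classes are assigned greedily by
genomic deficit against the target fractions under a banding-order
constraint (no same-class neighbours; euchromatin flanked by
heterochromatin).  Every chromosome is guaranteed at least one
euchromatic zone so that the induced-only variant can replicate it.
Deviation of realized fractions beyond `fraction_tolerance` (default 2
points; necessarily looser for toy genomes whose zones are a large
fraction of their length) is an error, not a warning.

What the generator does **not** emulate: the real Giemsa mosaic contains
many sub-megabase bands — small euchromatic islands inside heterochromatin
and vice versa — as well as centromere-specific structure and the
homogeneous facultative inactive X.  These features seed additional
origin firings in late-replicating regions.  Tests passing on the
synthetic genome therefore validate the kinetics engine, not the fine
structure of any real genome; statistics that depend on the full shape of
the inter-origin-distance distribution (notably the bootstrap comparison
against the DNA-combing mean of 188 kbp) are sensitive to exactly this
fine structure.  Users with access to a UCSC cytoBand file and a
karyotype table can substitute the real layout via `parse_cytoband()` and
`apply_karyotype()` (the inactive X is collapsed to a single facultative
zone).

## Chromatin folding

Chromosomes are Gaussian bead-spring chains without volume exclusion, one
bead per 100 kbp (a coarse 1 bead/Mbp mode is used by the test suite),
confined to an oblate ellipsoid (semi-axes 7.5 × 5 × 3.5 µm) containing
two impenetrable spherical nucleoli (radius 1.35 µm, the midpoint of the
1.2–1.5 µm range, placed at ±r_x/2 on the long axis).  Four potential
terms:

1. **chain** springs between consecutive beads with class-specific
   constants (10⁻⁸ EU, 5·10⁻⁷ FAC, 3·10⁻⁶ CON); a bond between beads of
   different classes uses the softer constant;
2. **loop** springs (5·10⁻⁷) between 5,000 randomly linked non-adjacent
   bead pairs, allocated to chromosomes by length, with geometric spans
   averaging 2 Mbp (minimum two beads);
3. **repulsion** between chromosome centres of geometry,
   `kappa_R * W_m * W_n / d` with bead-count weights (10⁻⁴), keeping
   territories apart;
4. **periphery**: facultative beads feel `-kappa_N / (d + r_soft)` with
   `d` the distance to the nearest of the nuclear envelope and the
   nucleolar surfaces (`kappa_N = 30`, `r_soft = 1` µm prevents
   divergence); constitutive beads feel the same form with reversed sign
   and `kappa_N = 15`.

The published constants come without units; this package fixes the scale
as: positions in µm, energies in kT at 290 K, chain/loop constants per
nm², repulsion per nm, periphery strengths per µm.  This choice makes
euchromatin effectively confinement-dominated (equilibrium bond length
exceeds the nucleus) and constitutive heterochromatin compact (~1 µm
bonds), reproducing the intended compaction ordering; it is the largest
single reconstruction in the package and every constant is a parameter.
The envelope distance is measured along the radial ray,
`|x| (1 - m) / m` with `m` the ellipsoid norm.

Sampling is single-bead Metropolis at 290 K: isotropic Gaussian
proposals, out-of-bounds moves rejected outright, otherwise accepted with
`min(1, exp(-dU / kT))`.  The step size is auto-tuned to a 30–50%
acceptance rate during the first fifth of the sweeps.  Energy changes are
incremental (bonds and loops touching the bead, the bead's periphery
term, and the centre-shift contribution to the repulsion) against cached
chromosome centre sums, and are validated against full recomputation.
Initial conformations seed each chromosome as a Gaussian blob (s.d.
0.8 µm) around a random interior point.  Convergence is flagged when the
energy slope over the final 20% of sweeps is statistically zero; the
test suite checks the sampler against the analytic Boltzmann
distribution of a harmonic dimer rather than trusting the flag.

## In-silico microscopy

Fork positions are accumulated over a 15-minute window (the experimental
staining time), sampled from engine snapshots — the package records them
every 60 s within rendering windows — and mapped to 3D by linear
interpolation between flanking bead centres (clamped at chromosome
ends).  The labelled point cloud is voxelized at 40 × 40 × 125 nm with
half-open binning, blurred by a separable Gaussian (default sigmas 2, 2,
1 voxels; the published work states a blur without a value) with
edge-renormalized kernels, and projected as a maximum-intensity
z-projection or the middle z-section.  Colour overlays put constitutive
heterochromatin in red, facultative in green, euchromatin in blue.

## Derived statistics and comparison procedures

* Inter-origin distances: successive differences of sorted fired-origin
  positions per chromosome, never across barriers.
* 1D clusters: maximal runs of active forks with adjacent gaps strictly
  below 1 Mbp and no intervening barrier; cluster size is the genomic
  span (singletons count with span 0).  The cluster count `N_c` feeds the
  cluster-front ("wave") speed `v_w = nu * L_max / (2 N_c)`.
* Timing profiles: a position's replication time is the firing time of
  its replicon's origin plus the fork travel time over the separation,
  averaged position-wise over runs; correlations with external profiles
  are plain Pearson (signs may oppose by convention; compare `|r|`).
* Bootstrap mean test: 10,000 subsets of 50 distances (without
  replacement within a subset); `P` is the smaller of the fractions of
  subset means below/above the 188 kbp reference, ties split evenly,
  reported as an upper bound `1/repetitions` when a fraction is zero.
* Histogram comparisons: chi-square on counts with the simulated
  histogram scaled to the observed total, and Kullback–Leibler on
  frequencies; empty simulated bins receive a 0.5 pseudo-count in both
  so the measures stay finite.  Default binning: 20 kbp bins over
  [0, 800] kbp.
* `sweep_inhibition_distance()` re-runs the simulation across `d_i`
  values (5 kbp steps over 0–120 kbp by default) and reports both
  measures plus total firings.

## Numerical choices and degenerate inputs

Coordinates are 0-based, half-open, continuous (fork positions are
fractional); synthetic zone boundaries are rounded to integer bp.
Boundary conventions: firing at exactly `d_i` is allowed; a Gaussian
value exactly at the cutoff is kept; a position equal to a zone end
belongs to the next zone.  Simultaneous events are ordered by kind then
position.  A run that can no longer progress (no active forks, no
positive-probability candidate, DNA left) raises a diagnostic error
rather than spinning.  All randomness in a run flows from a single seed:
layout generation and origin placement through R's RNG (saved and
restored around every seeded helper), the engine and sampler through
their own 64-bit generators seeded from the same value, with draw order
fixed as documented in the firing round.

## Problem sizes

The unit and property tests run on ~40 Mbp, 4-chromosome toy genomes
(seconds), fixed-timestep oracle scenarios on ~100 kbp chromosomes at
`dt = 0.1` s, and coarse 1 bead/Mbp foldings of a few hundred beads.  The
acceptance checks run the full 10.36 Gbp genome with default parameters
over ten seeds (~25 s per run in the compiled engine), plus five runs
with the inhibition disabled.

## Known limitations

* The synthetic genome's zone-size floor (~0.2 Mbp) omits the sub-Mbp
  band structure of real karyotypes; distance-distribution-shape
  statistics inherit this (see above).
* The folding energy scale is a reconstruction; only orderings and
  qualitative localization are asserted, not absolute compaction.
* No volume exclusion between beads, no coupling of folding dynamics to
  replication (the conformation is static during rendering), no
  stalled-fork or re-licensing biology, no sequence-specific origin
  placement, and no replication factories — deliberately, as these are
  outside the model.
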