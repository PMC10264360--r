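---
title: "Modelling a holocentromere built from a few megabase-scale units"
author: "holosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a holocentromere built from a few megabase-scale units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holosim)
```

## The scientific problem

Most holocentric species distribute hundreds of small centromere units
along each chromatid. The lilioid plant *Chionographis japonica* is
different: each of its 12 chromosomes carries only 7–11 CENH3-positive
centromere units, each a megabase-scale satellite array (0.24–4.46 Mb),
evenly spaced at roughly 10 Mb intervals. At interphase these units cluster
into a few chromocenters, like monocentric plants; at prometaphase they
re-organise into a line-like holocentromere on the poleward face of each
chromatid. `holosim` provides the computational toolbox for studying this
organisation: a coarse-grained polymer model of the condensation process,
the interval arithmetic that calls centromere units from CENH3 ChIP
domains, a dyad-symmetry scanner for the centromeric satellite monomers,
and synthetic-data generators that make every stage testable without any
external dataset.

## The polymer model

A chromatid is a beads-on-a-string fiber: one bead per nucleosome with its
linker (200 bp), so the reference model of a ~20 Mb chromatid has 100,000
beads (`default_chromatid_layout()`). Eight 442-kb centromere units are
evenly spaced so that internal gaps are equal and each terminal flank is
half a gap; inside each unit 1325 beads (~60% of its 2210 beads) are typed
centromeric. The per-unit centromeric count is a direct parameter: 60% of
2210 rounds to 1326, but the model convention is 1325, and the fraction is
treated as approximate.

Three generic forces give the fiber chromatin-like motion:

* a harmonic bond between consecutive beads
  (\(U = \tfrac12 k_b (x - x_0)^2\), defaults \(k_b = 10\,k_BT/\mathrm{nm}^2\),
  \(x_0 = 10\) nm, the nucleosome scale);
* a bending energy \(k_\theta (1 - \cos\theta)\) on consecutive triplets
  (default \(k_\theta = 2\,k_BT\)), giving a semiflexible 10-nm fiber;
* a soft-core attractive–repulsive quartic between non-consecutive beads,
  \(U(x) = a + b\,((x/r_m)^4 - 2 (x/r_m)^2)\) with a finite core
  \(a = 5\,k_BT\) at contact so that the fiber can cross itself
  (topoisomerase-II mimicry).

Pairs of *centromeric* beads instead interact through a two-branch quartic
(`cen_pair_potential()`): the core branch (scale 8 nm) and a tail branch
(scale 20 nm, shift 0.6) that meet with equal value and slope at the 8-nm
global minimum of \(-1\,k_BT\). The tail rises more slowly than the core
branch would, so centromeric nucleosomes attract each other from larger
distances and sit closer and more firmly than generic pairs — the selective
stickiness that forms chromocenters.

Two numerical choices deserve comment:

* **Tail cutoff.** The tail branch grows without bound (\(u^4\)), which
  would exert enormous long-range forces. The potential is therefore held
  constant beyond `r_cut = 60` nm (zero force). We hold rather than shift
  because the printed constants pin the potential's values (5 \(k_BT\) at
  contact, \(-1\,k_BT\) at 8 nm); the engine's *logged* energy trace uses
  the cutoff-shifted form so that far pairs contribute zero and traces
  remain interpretable.
* **Generic well.** The generic potential's well coefficient (default
  5.5 \(k_BT\), minimum \(-0.5\,k_BT\) at 10 nm) must exceed the 5-\(k_BT\)
  core for the quartic to cross zero, where it is truncated continuously;
  it must stay below the centromeric coefficient (6) so that centromeric
  pairs are strictly the more attractive, closer-acting ones. Values at
  contact and at the minimum follow the convention
  `core_height - well_depth`.

## Loop extrusion

SMC-like loop extruders live on the 1D bead lattice (`seed_extruders()`,
`extrusion_sweep()`). Each extruder starts with its legs on adjacent
intercentromeric beads; every sweep, each leg steps one bead outward
(probability `p_step`, default 1 — the simplest kinetics consistent with
processive extrusion; stochastic stepping is a config option). Extruders
are prohibited inside centromere units: a leg whose next step would enter
a unit instead halts permanently ("anchors") on the boundary-adjacent
bead. Legs cannot pass or share a bead (the standard SMC-lattice collision
convention), and a leg at a fiber end is blocked but not anchored. All
extruders load at sweep 0 with no turnover: anchoring implies no
unloading, and no loading/unloading rates are part of the model. With
deterministic stepping, a single extruder on a gap of \(g\) beads reaches
steady state within \(g\) sweeps.

## Langevin engine and phase protocol

The 3D dynamics is overdamped Langevin in reduced units
(\(k_BT = 1\), nm, friction 1). The integrator is the
Leimkuhler–Matthews scheme — the thermal noise of consecutive steps is
averaged — because its configurational sampling bias is \(O(\Delta t^2)\);
a plain Euler–Maruyama step at the default \(\Delta t = 0.01\) would bias
the bond-fluctuation variance by about \(k_b \Delta t / 2\gamma = 5\%\),
exactly the margin our thermodynamic validation tests demand. The default
timestep 0.01 is chosen for stability against the steepest default force
(the bond term plus the centromeric tail near its cutoff); 0.02 visibly
stretches bonds beyond the 3\(\times x_0\) integrity bound and is rejected.

The phase protocol mirrors the study design (`phase_protocol()`): an
interphase phase (default 5,000,000 steps) with spherical confinement and
no extrusion, then a condensation phase (up to 25,000,000 total steps)
with confinement off and loop extrusion coupled in. The confinement sphere
volume is the average G1 root-nucleus volume of *C. japonica*
(110.57 µm³) scaled by the fiber's share of the 2C genome,
`total_bp / (2 × 1368 Mb)` — the proportionality constant is not fixed by
the study, so it is an explicit config entry. During condensation, one 1D
sweep advances the extruders every `coupling_interval` 3D steps and the
leg pairs are refreshed as harmonic bonds; the default interval keeps the
1D lattice at steady state within the first fifth of the condensation
phase, mirroring a 1D-first-then-3D coupling.

## What the simulation shows, and at what scale

Interphase: centromeric beads collapse into chromocenter-like bodies —
the local density around centromeric beads exceeds the intercentromeric
fiber (`local_density_ratio()` well above 1) — and units sharing a
chromocenter appear as single-linkage clusters of unit centroids
(`cluster_units()`), sometimes fewer clusters than units, as seen in
nuclei. Condensation: loops accumulate around the chromocenters, giving a
non-uniformly condensed intermediate, and the unit necklace stretches into
a line-like holocentromere, which we quantify as the principal-axis
variance share of the centromeric beads (`linearity_score()`; 1/3 for an
isotropic cloud, 1 on a line). The study reports no quantitative "line"
definition; this statistic is our declared operationalisation, as is the
single-linkage threshold `d_link = 24` nm (three times the centromeric
minimum distance: beyond direct attraction, below the confinement scale).

Package tests exercise a proportionally scaled-down chromatid
(`scaled_chromatid_layout()`): 2,000 beads, eight 44-bead units with 26
centromeric beads each, 5×10⁴ interphase plus 1.5×10⁵ condensation steps,
five to ten random-conformation replicates. These sizes are the package's
desk-scale defaults; the full reference protocol above remains the config
default and is cluster-scale. One scale-down choice is deliberate: the
extruder count. Proportional scaling (500 × 2000/100000 = 10) leaves some
intercentromeric gaps without any extruder (Poisson loading), a regime the
full-scale model never enters (~55 extruders per gap); an un-looped gap
lets neighbouring chromocenters fuse instead of being spaced by loop
bulges. Desk-scale runs therefore load 24 extruders (~3 per gap), the
smallest count that keeps every gap reliably looped. Likewise the
1D-sweep coupling is every 200 steps at desk scale so that reeling a
10-nm bond per sweep does not over-stretch the chain.

What passing desk-scale tests do **not** show: equilibrium at full scale,
nucleus-level chromocenter counts (those are whole-nucleus, 24-chromatid
quantities; the model is a single chromatid), or any sequence-level
behaviour of the satellite arrays — beads are typed, not sequenced.

## Centromere-unit calling and statistics

The annotation module re-implements the unit-calling rules on BED-style
intervals: keep only regions supported by both peak callers (base-pair
intersection — whether the study kept whole peaks or base-pair overlaps is
not stated; base-pair intersection is our declared choice), merge domains
separated by **less than** 500 kb, then discard domains shorter than 1 kb
(a domain of exactly 1 kb survives; a gap of exactly 500 kb is not
merged). The order — intersect, merge, filter — follows the pipeline's
narrative order and is exposed as parameters. Statistics (`unit_stats()`)
cover unit counts, lengths, inter-unit gaps, units per Mb, the Pearson
correlation of unit length with the mean of its flanking gaps (terminal
units use their single internal gap), and mean nearest-gene distance
(zero when abutting). Interval arithmetic runs on GenomicRanges; the test
suite checks every operation against an independent per-base set oracle.

## Dyad-symmetry scanning

The centromeric satellite monomers (23 and 28 bp) contain dyad symmetries,
and a conserved 8-bp dyad can form a hairpin between neighbouring
monomers. `find_dyads()` reports every maximal, mismatch-free inverted
repeat with arm ≥ `min_arm` (default 4) and loop ≤ `max_loop` (default
10); maximality means the arms extend neither outward nor inward.
`dimer_hairpin()` scans the head-to-tail dimer and keeps dyads straddling
the monomer junction (default arm 8). No thermodynamic folding is
attempted — "hairpin-capable" is a structural, not energetic, statement.
The parameters behind the published per-monomer dyad counts are not
stated, so defaults are exposed rather than fitted.

## Synthetic data

`gen_genome_truth()` draws per-chromosome architectures in the reported
regime: 7–11 units per chromosome, truncated-lognormal unit lengths
(mean 1.89 Mb within 0.24–4.46 Mb), truncated-normal gaps (mean 9.97 Mb,
sd 2.5 Mb, floor 1 Mb — the floor keeps distinct units above the merge
threshold so calling is well-posed). Only the ranges and means come from
the reported statistics; the distribution families are our emulation
choice. `fragment_truth()` breaks units with Poisson-placed interruptions
strictly shorter than the merge threshold and pieces of at least 1 kb, so
`call_units()` recovers the planted truth exactly — a designed round-trip
guarantee, enforced by parameter validation. `gen_two_callers()` places
caller-specific false positives in disjoint halves of the inter-peak
space so that, absent jitter and drop-outs, the dual-caller intersection
equals the raw peaks exactly. `gen_monomer_with_dyads()` plants exact
maximal dyads (flanking and innermost-loop bases are made non-pairing) and
can make the monomer suffix the reverse complement of its prefix so the
dimer carries a junction-spanning hairpin arm of exactly the requested
length. Every generator is a pure function of its parameters and seed.

## Known limitations

* Single chromatid, no nucleus crowding by other chromosomes; interphase
  confinement stands in for the nuclear environment.
* The generic-force constants (bond, bend, soft-core) are declared
  substitutes — the model family is fixed by the three-force design, but
  the originally used constants are not restated in the study we follow.
* Deterministic extrusion kinetics by default; no extruder turnover.
* Desk-scale runs are far from full-scale equilibration; the package's
  emergent-property tests are directional (ratios, ordering of scores),
  not quantitative reproductions.
* In a minority of desk-scale replicates the tight scaled confinement
  fuses most units into one or two chromocenters during interphase, and
  that ball persists through condensation instead of stretching into a
  line; the linearity comparison is therefore made on the median across
  replicates, not per seed.
* The dyad scanner is exact-match only by default; degenerate or
  mismatched arms are out of scope.

## A short worked example

```{r example, eval = FALSE}
lay <- scaled_chromatid_layout(2000)
pr <- phase_protocol(interphase_steps = 5e4, total_steps = 2e5,
                     coupling_interval = 200, n_extruders = 24)
conf <- run_interphase(lay, pr, seed = 1)
local_density_ratio(conf, lay, r_nbr = 30)   # > 1: units condensed
cluster_units(conf, lay)$n_clusters          # <= 8 chromocenters
cr <- run_condensation(conf, lay, pr, seed = 1)
linearity_score(cr$conformation, lay)        # rises toward 1
```
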