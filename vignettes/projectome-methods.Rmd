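---
title: "Methods: single-neuron projectome quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-neuron projectome quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, which
conventions it fixes where the field leaves room, and what its synthetic
data can and cannot show about real reconstructions.

## The analysis

The unit of analysis is a complete single-neuron reconstruction: a rooted
tree of 3D nodes (standard SWC, micrometers) whose root is the soma and
whose nodes are typed soma / axon / dendrite. Against a voxelized region
annotation (a label volume plus a region ontology and an axis-aligned
midline plane), the pipeline computes, per neuron:

1. **Morphometrics** — axonal and dendritic cable length, branch count and
   terminal-tip count.
2. **Projection strengths** — the fraction of total axonal cable inside
   each brain region, the field's operational proxy for output strength
   (axonal length per area correlates with synapse counts).
3. **Hemisphere decomposition** — ipsilateral vs contralateral cable
   relative to the soma side.
4. **Classification** — callosal (CPN) vs associative (APN)
   intratelencephalic subclass, plus a reproducible grouping of projection
   profiles into categories.
5. **Group statistics** — mean ± s.e.m. tables and pooled Student's
   *t* comparisons across soma groups (MOs layer 5, MOs layer 2/3, PL,
   ORBm) and subclasses.

## Conventions the package fixes

Several quantities are conventionally under-specified; the package fixes
them once, and the test suite enforces them:

* **Edge class is the child's class.** The soma→axon stem edge is axonal
  cable. This is the only assignment that is unambiguous at class
  transitions.
* **Branch = edge of the condensed class subtree** (maximal unbranched
  path between stem, branch point and tip). Tips and branch points are
  counted on the class-restricted subforest (zero / ≥ 2 same-class
  children), so `branches = tips + branchpoints` holds identically, and a
  strictly bifurcating single-stem arbor satisfies `branches = 2·tips − 1`.
  This is the convention under which published group means for axonal tip
  and branch counts (≈ 1483 and ≈ 2964 for deep-layer cells) are mutually
  consistent; a compartment-based count would not be.
* **Half-open voxels.** Voxel `(i,j,k)` covers
  `[origin + i·d, origin + (i+1)·d)`; a point exactly on an interior
  boundary belongs to the higher-index voxel. Fixed so lookups are
  bit-exact and testable.
* **Midpoint booking.** Each axonal edge is subdivided into pieces no
  longer than `step` (default: the smallest voxel edge) and each piece's
  full length is booked to the region and hemisphere at its midpoint.
  Unlike polygon clipping against voxel faces this conserves total length
  exactly by construction; it converges to clipping as `step → 0`, and on
  axis-aligned fixtures the split error is bounded by one step. Halving
  the step moves region totals by well under 1% on the test battery.
* **The background bucket is never renormalized away.** Cable outside any
  labeled region (or outside the volume) is reported under id `0`, and
  the projection-strength denominator is the *total* axonal length.
  Printed ipsi + contra percentages may therefore legitimately sum below
  100%. A `include_background = FALSE` option renormalizes over labeled
  cable only, for users who want the other reading.
* **Ties in majority downsampling** break toward the smallest label id;
  edge blocks may be partial; the origin never moves.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `step_um` | smallest voxel edge | µm | cable subdivision for region/hemisphere booking |
| `min_contra_mm` | 1.0 | mm | contralateral cable needed to call a neuron CPN |
| `theta` | 0.05 | fraction | strength threshold for a region to count as a target |
| `jaccard_cutoff` | 0.5 | — | single-linkage similarity to merge two neurons' categories |
| `downsample_factors` | (1,1,1) | — | majority-label downsampling of the annotation volume |
| `welch` | FALSE | — | Welch instead of pooled Student's t |

The CPN definition deserves a note: anatomically a CPN is an IT neuron
whose axon crosses through the corpus callosum. Published work states no
minimum contralateral cable, so the package operationalizes the class as
contralateral cable ≥ 1 mm and reports the geometric cc-routing check
(`crossed_via_cc`) separately rather than folding it into the definition —
a stray sub-threshold crossing should not flip a neuron's class. On the
synthetic populations the two notions coincide (CPN specs allocate tens of
millimetres contralaterally; APN specs allocate none).

The three-way categorization of projection patterns reported in
single-neuron studies is typically qualitative ("axons extended caudally…").
The package replaces it with a deterministic rule — binarize strengths at
`theta`, group by single-linkage Jaccard ≥ cutoff over target sets — which
is permutation-equivariant and reproducible, at the cost of fidelity to any
particular by-eye grouping. Single linkage chains aggressively: on profiles
that share a large common repertoire (motor cortex + striatum in nearly
every IT cell, as in the demo population) it can merge everything into one
category. That is a faithful property of the rule, not a bug; users wanting
finer categories should raise `theta` or the cutoff, or exclude
always-shared regions.

## The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known truth; it emulates the *statistical regimes* of real IT
reconstructions, not their visual appearance.

**Atlas.** An 8 × 8 × 4 mm brain at 100 µm voxels: mirror-symmetric box
regions for MOs (with L1 / L2/3 / L5 slabs), PL, ORBm (layered), ACA, AI,
SS, VIS, RSP, ENT, CP and BLA, plus a corpus-callosum band straddling the
midline at white-matter depth. Box bounds are multiples of the voxel size,
so the left hemisphere is the exact voxel-wise mirror of the right.

**Neurons.** Per neuron: one axon stem; a lightly jittered shaft to each
target region (contralateral targets are routed through a waypoint inside
the cc band, so callosal cells demonstrably cross it); inside each target
box a bifurcating persistent random walk whose segment lengths are
exponential with mean `1/branching-rate`, reflected at the box walls,
consuming that target's cable allocation; and a local dendritic arbor
around the soma. Cable is allocated to targets in proportion to the spec
weights; each target's shaft is charged against its own allocation (with a
small floor for under-funded targets) so realized fractions track the
requested weights. Routing cable is booked to whatever regions it
traverses — like real axons passing through white matter — and the
generator records the realized per-region fractions (fine subdivision at
one fifth of a voxel) as ground truth. That choice makes recovery tests
exact up to discretization: the quantifier is compared against what was
actually laid down, not against the requested weights, separating
quantification error from growth noise.

**Regimes.** Group presets are parameterized from published summary rows:
per-group axonal and dendritic totals are drawn from truncated normals
with sd = s.e.m.·√n and location calibrated (one-dimensional monotone
solve) so the *truncated* mean equals the printed group mean — deep-layer
MOs cells ≈ 270 mm of axon truncated to the printed range
[180.04, 318.43] mm, upper-layer groups ≈ 65–70 mm, dendrites ≈ 5.5–7.4 mm.
Branching rates are printed branches per printed mm (≈ 11 per mm for deep
cells); because routing shafts are unbranched, the arbor rate is scaled up
by the routing share so the whole-cell rate lands near the target. Class
mixes follow the study design: all 6 deep MOs cells callosal, 10/17 in MOs
layer 2/3, 1/6 in PL, 5/7 in ORBm. Per-neuron target weights are preset
profiles with Dirichlet jitter (concentration 60) — chosen once as
plausible IT repertoires (striatum-dominant for deep cells, mixed
cortico-cortical for upper layers).

**What passing tests do and do not show.** The generator produces box
arbors with isotropic tortuosity, exact class purity (axon never reverts
to dendrite), no reconstruction noise, and a geometrically clean midline.
Tests passing on it demonstrate that the quantification machinery is
correct — conservation, recovery, symmetry, determinism — not that any
biological claim about real MOs neurons is reproduced. Real
reconstructions bring soma contours, unlabeled neurite types, atlas
registration error and annotation gaps; of these, only the first two are
exercised (multi-node somas and `OTHER`-typed nodes appear in the random
test battery).

## Numerical choices and degenerate inputs

* Lengths are computed in µm and reported in mm with no intermediate
  rounding; SWC is written at full double precision (`%.17g`), so
  write→read roundtrips are exact and repeated writes byte-identical.
* Zero-length edges are legal and contribute zero cable.
* A neuron with no axon is flagged (`no_axon`), not dropped; projection
  operations on it raise a classed `empty_axon` error.
* `sem` of a single observation is `NA` (flagged in summaries); a
  two-sample test between two constant equal samples has undefined *t*
  and is returned with `degenerate = TRUE` rather than raised.
* Category ids are numbered by first member in input order, making the
  grouping deterministic and permutation-equivariant.
* All simulation randomness derives from explicit seeds; generator
  functions restore the caller's RNG state.

## Problem sizes used in tests and the acceptance script

The test suite generates its own inputs at every run: ~500 random trees of
up to 500 nodes for the morphometry oracle battery, 20 seeded upper-layer
neurons (~70 mm of axon each) for strength/class recovery, and small
(2 + 3 + 2 + 2) populations for the pipeline tests. The acceptance script
runs the full 36-neuron demo design (≈ 3,700 mm of total cable) — chosen
as the smallest population that exercises all four soma groups at the
study's sizes. The whole suite completes in well under a minute on one
core.

## Known limitations

* Atlas regions are axis-aligned boxes; no curved boundaries, no
  registration step (out of scope by design — the annotation volume is an
  input).
* The arbor growth model is not biophysical: no growth-cone dynamics, no
  tiling, no self-avoidance; branch angles are isotropic perturbations.
* Multifurcations produced by budget truncation make a few arbors deviate
  from strict bifurcation, so `branches = 2·tips − 1` holds only
  approximately on generated populations (the exact identity
  `branches = tips + branchpoints` always holds).
* The Jaccard categorization is a stand-in for qualitative published
  groupings and will not reproduce them on real data without tuning.
* AM (Amira) format, multi-neuron SWC archives, and repair of broken
  topologies are out of scope; `validate_morphology` reports defects, it
  does not fix them.
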