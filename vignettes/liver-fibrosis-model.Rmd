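---
title: "An agent-based model of liver lobule inflammation and fibrosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of liver lobule inflammation and fibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`lobulesim` simulates a two-dimensional patch of liver tissue as a honeycomb
of hexagonal lobules. The structural skeleton consists of portal-triad nodes
at every hexagon vertex and one septum per edge. Each septum is a pair of
boundary sub-segments laid side by side and joined by a prismatic joint
(they may slide along their common axis, so the septum can telescope), and
each sub-segment is attached to its portal triad by a revolute joint (it may
rotate about the node). The skeleton is held in reduced coordinates: a
sub-segment is always anchored at its node and directed along the
node-to-node axis, so both joint constraints are satisfied exactly by
construction, and the prismatic slide appears as a bounded node-distance
window.

Agents live in continuous space on this skeleton:

* **Hepatocytes** (disks, one diameter = one length unit) fill the lobules.
  They are long-lived, detect empty neighbouring space and replicate into
  it; next to collagen a cell cannot replicate more than twice (replicative
  senescence).
* **Dead hepatocytes** are produced by toxic injury and by above-threshold
  TNF-α (a lumped bystander effect standing in for T-cell biology). They
  keep occupying space until phagocytized, and while uncleared they release
  the damage signal HMGB1 after a short delay.
* **Kupffer cells** are resident macrophages. On engulfing a dead cell they
  become activated and begin secreting TNF-α and TGF-β1, mixed by a
  phenotype weight `m` that shifts from M1 (`m = 0`, pure TNF-α) toward M2
  (`m = 1`, pure TGF-β1) by a fixed increment per phagocytosis event.
  HMGB1 hot spots recruit circulating monocytes as fresh activated M1
  cells, at most one Kupffer cell per grid cell (extravasation saturates).
* **Fibrogenic cells** — hepatic stellate cells in the lobule interior and
  portal fibroblasts at the triads — transform irreversibly into
  myofibroblasts when they detect TNF-α or HMGB1. Myofibroblasts detecting
  TGF-β1 proliferate (contact-inhibited) and deposit collagen onto existing
  matrix structure: septa, triads, or earlier deposits within a periportal
  band.
* **Collagen deposits** are permanent disks anchored to structure. Only
  hepatocytes, dead cells, septa, triads and collagen collide; Kupffer and
  fibrogenic cells co-occupy space freely.

The three mediators (TNF-α, TGF-β1, HMGB1) are concentration grids at one
cell per hepatocyte diameter, advanced by an explicit 5-point diffusion
stencil with zero-flux boundaries followed by multiplicative degradation.
Agents "detect" a factor where the local concentration is at or above the
field's threshold (`>=` convention).

A simulation step applies, in fixed order: scheduled injury pulse → agent
rules (hepatocytes, Kupffer cells, fibrogenic cells, HMGB1 release) in
randomized agent order → monocyte recruitment → field update → mechanics
(collision relaxation against the septal skeleton) → census.

## Virtual elastography

Tissue stiffness is scored without perturbing the simulation: on a deep
copy, every hepatocyte and dead cell is shrunk by 5% (standing in for
cellular compressibility, so a fully packed patch can compress at all), all
outer-border nodes are pinned, and every internal node (three adjoining
septa, not on the border) receives an inward impulse toward the patch
centroid. After one overdamped mechanical step the mean displacement
magnitude of the internal nodes is reported; the copy is discarded and the
original state is bit-identical before and after. Larger displacement means
more pliable tissue.

Two numerical choices matter here. First, node corrections from the many
simultaneous contacts are averaged per relaxation sweep (Jacobi style);
applying each correction in full, sequentially, lets a node accumulate
unbounded displacement in densely fibrotic states, which inverts the sign
of the measurement. Second, the impulse (default 2 cell diameters of free
motion) is applied in 10 substeps with relaxation in between; a single jump
would tunnel the swept septa past thin contacts and read free motion
regardless of the tissue. With these choices the probe responds to the
packing of the first few periportal cell layers: removing periportal cells
raises the reading, and dense collagen cords along the septa lower it
sharply.

## The stated world (defaults) and why

No kinetic constants are hard-coded from data; the default configuration is
a single coherent "stated world" calibrated so the model reproduces the
emergent behaviours the underlying biology is known for. The key choices:

* **Geometry.** 4 × 4 lobules, hexagon side 10.60, cell diameter 1. The
  side length is calibrated so the spiral fill (an Archimedean spiral at
  one-diameter arc steps, densified by the contact-replication rule until
  no cell finds empty space) emerges at ≈ 3,857 hepatocytes; Kupffer cells
  and stellate cells are then 15/60 and 5/60 of that count (964 and 321).
* **Injury.** A toxic pulse every 25 steps kills each hepatocyte in the
  lobule cross-section (radius 9.1, just under the inradius) with
  probability 0.1. A narrowly centrilobular pulse cannot produce the early
  whole-tissue softening that elastography shows, because the probe senses
  the periportal layers; the wide, mild pulse keeps total injury per cycle
  the same while distributing it across the lobule.
* **Regeneration is slow** (replication attempt probability 0.1 per step):
  liver regrowth takes days to weeks while an injury cycle is days, so
  necrotic porosity persists long enough to be measurable. This is what
  produces the early rise in pliability.
* **Kupffer kinetics.** Engulfment takes time (probability 0.07 per
  adjacent step), so clearance of a necrotic burst is gradual and can be
  inadequate — exactly the regime in which HMGB1 accumulates and recruits
  monocytes. Activated Kupffer cells are long-lived (800–1200 steps), so
  activation accumulates: the activated census rises as residents convert
  and recruits arrive, and saturates when the recruitment zone is occupied
  and the reachable resident pool is exhausted. With these rates the
  50-step/2% moving-window criterion detects the plateau at ≈ step 300.
* **Mediators.** TNF-α is short-ranged (degradation 0.12 per step), keeping
  the bystander-death zone near its sources; TGF-β1 and HMGB1 are
  long-lived (0.03 and 0.04), letting the anti-inflammatory and fibrogenic
  signals reach the periportal zone. Fibrogenic cells respond at 40% of
  the field threshold — fibroblasts are far more sensitive to these
  cytokines than the lumped death rule — which separates the fibrogenic
  range from the killing range.
* **Graded TGF-β1 couplings.** Above threshold, TGF-β1's damping of
  Kupffer TNF-α output and its drive of myofibroblast deposition and
  proliferation follow saturating dose–response curves (half-saturation
  10 concentration units). Purely binary above-threshold gating saturates
  at baseline, in which case enhancing M2 output could change nothing —
  contradicting the known therapy phenotype (less TNF-α, substantially
  more collagen under M2 enhancement).
* **Collagen placement.** Deposits go to the nearest admissible site on an
  anchor surface. The tissue yields: a deposit may penetrate pushable
  cells by up to 0.4 diameters and the per-step mechanics relaxes the
  overlap (cells are displaced; the new matrix is not). A strict
  empty-site rule can never fire in a contact-packed periportal zone and
  would forbid fibrosis outright. Chains extend the scaffold only within
  2.5 diameters of the skeleton, so cords thicken and bridge along septa
  (periportal, then bridging fibrosis) instead of invading the lobule
  centre and strangling regeneration.

## What the generator emulates — and what it does not

The synthetic world reproduces: baseline homeostasis (uninjured runs hold
every census within ±5% over 500 steps — in fact they are nearly static by
construction); the inflammatory cascade injury → activation → M1-to-M2
succession (TNF-α total peaks before TGF-β1 total); an activated-Kupffer
plateau near step 300; periportal-before-bridging collagen that only ever
grows; an early rise then monotone fall of elastic displacement; and the
three-way therapy ordering (anti-TNF < baseline < enhanced M2 for final
collagen, with TNF-α reduced under both therapies).

It does not emulate: real-time units (steps are abstract; no mapping to the
dosing calendar of a toxic-injury protocol is claimed); histological
texture beyond the draw-list snapshots; vasculature, zonated metabolism, or
fibrosis regression (collagen is never removed); stiffness in physical
units (displacement is "relative to set simulation space"); or 3-D tissue.
A green test therefore establishes internal consistency of this stated
world, not quantitative agreement with any particular animal series.

## Numerical choices and degenerate inputs

* Collision tolerance is 10⁻³ cell diameters; relaxation is a
  deterministic sorted-id sweep, chunked with early exit once the worst
  residual is below tolerance. A residual above 0.3 diameters aborts the
  run with a state dump (it signals a scheduler bug, not physics).
* The explicit diffusion scheme requires `diffusion ≤ 0.25`; construction
  rejects anything larger. Mass is conserved to better than 10⁻⁹ relative
  under zero degradation.
* Threshold comparisons use `>=`. Tie-breaking for replication and
  deposition targets is uniform random from the simulation's RNG stream.
* One RNG stream per replicate (replicate `r` uses base seed + r − 1);
  the state carries the generator, so save/load/resume is exactly
  reproducible and paired seeds across scenarios give common random
  numbers for the therapy comparisons.
* Degenerate inputs: a lobule smaller than one cell fills with at most one
  hepatocyte; a single-lobule patch has no internal nodes and elastography
  raises an explicit "unmeasurable lattice" error; `cell_diameter >=
  hex_side` is rejected as infeasible packing.

## Known limitations

* The elastography statistic reads the periportal layers; centrilobular
  porosity deeper than a few cell diameters is invisible to it. This is a
  consequence of measuring a displacement-controlled impulse in an
  overdamped, contact-only medium.
* The skeleton does not deform during normal steps (nodes move only under
  the probe); lobular distortion by fibrosis is represented by collagen
  geometry, not by bent septa.
* Myofibroblasts never die and collagen is never degraded, so late-stage
  states are end-stage by construction.
* The steady-state detector's 2% window criterion is noise-limited for
  plateaus below a few hundred agents; the default world was deliberately
  built with an activated plateau in the thousands.
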