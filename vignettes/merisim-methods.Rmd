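---
title: "Model and methods behind merisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind merisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

merisim simulates a two-dimensional sheet of epithelial cells — the
epidermal layer at the summit of a plant shoot apical meristem is the
motivating system — as a spring network of wall junctions, and asks how
different *cell division rules* shape the tissue-scale statistics of
cell packing: the distribution of neighbor numbers, internal vertex
angles, cell shapes, and the neighbor-number/area relation known as
Lewis' law. This vignette documents the model, its parameters, the
numerical choices, and the places where the design was genuinely open.

## The mechanical model

Cells are polygons whose edges (cell walls) are linear springs joining
three-way wall junctions (vertices). Plant cells cannot slide past each
other, so topology changes only through division. The dynamics are
overdamped: each vertex moves with velocity equal to the total force on
it (the drag coefficient is absorbed into the time unit).

Three ingredients drive the dynamics:

* **Wall springs.** A wall of realized length $l$ and resting length
  $L^0$ exerts force $k\,(l - L^0)$ on each endpoint, pulling them
  together when stretched. $k$ = `spring_k` = 0.05.
* **Wall growth under tension.** Resting lengths grow irreversibly
  toward the realized length, $\dot L^0 = k_g\,\max(0,\, l - L^0)$,
  with $k_g$ = `growth_k` = 0.01 per time unit. Compressed walls do not
  shrink. This is what makes the tissue *grow* rather than merely
  stretch elastically.
* **Radial turgor/growth force.** Turgor pressure and the underlying
  tissue push the sheet outward. merisim's default is a force
  proportional to the position vector, $F_i = k_r\,x_i$ with $k_r$ =
  `radial_k` = 0.05, i.e. a uniform isotropic dilation field. A
  constant-magnitude variant ($k_r\,\hat x_i$) is available via
  `model_params(radial_mode = "constant")`; see *Design choices* for
  why it is not the default.

Cells divide when their area exceeds `area_threshold` = 1.0 (area
units); the planar sheet is only a faithful picture of the curved
meristem near its summit, so cells whose centroids drift beyond
`radius_threshold` = 7.0 are removed with any walls and vertices they
alone used. Between the division threshold and the removal boundary the
tissue settles into a statistically steady state of roughly 220 cells
(about 170 of them interior) that turns over continuously.

## Division rules

A division rule is a pair of mechanisms. The **center** mechanism picks
a point in the mother cell: its area centroid (`COM`) or a uniform
random interior point (`Random`). The **direction** mechanism picks an
axial direction for the new wall:

* `ShortestPath` — the direction minimizing the chord length through
  the center (Errera's soap-film rule when combined with COM);
* `RandomDirection` — uniform on $[0, \pi)$;
* `Orthogonal` — perpendicular to the plane of the division that
  created the cell (random for founders), as observed in meristem
  lineages;
* `StrainPerpendicular` — perpendicular to the cell's strain axis
  (Hofmeister's rule). The strain axis is the strain-weighted axial
  circular mean over the cell's walls,
  $\theta = \tfrac12 \operatorname{atan2}\big(\sum_w s_w \sin 2\phi_w,
  \sum_w s_w \cos 2\phi_w\big)$, with $s_w$ the relative extension of
  wall $w$ clipped at zero (a signed variant is available; in a growing
  tissue every wall is under tension, so the two coincide). If every
  strain vanishes the direction falls back to random.

The new wall runs along the chord of the cell polygon through the
center. Each cut wall is replaced by two walls whose resting lengths
split the old one in proportion to the realized sub-lengths; the new
wall is born unstressed (resting length equal to its realized length).
If a new junction would land within `d_threshold` = 0.1 of an existing
junction — which would create a forbidden four-way junction — it slides
along its wall to exactly that distance; if the wall is shorter than
`2 * d_threshold` the division is aborted and retried at a later check,
once growth has lengthened the wall.

## Numerics

The equations of motion are integrated with an adaptive embedded
Cash–Karp Runge–Kutta 4(5) pair (relative tolerance $10^{-6}$, absolute
$10^{-8}$), written in the package rather than taken from an ODE
library because the event structure requires it: after *every accepted
step* the driver checks all cell areas against the division threshold
and all centroids against the removal radius, and any division or
removal changes the size of the state vector (all vertex coordinates
followed by all resting lengths), which general-purpose solvers do not
allow mid-run. The step is capped at `h_max` = 1.0, which bounds the
lag between event checks; at the default growth rates a cell can
overshoot the area threshold by only a few percent before it is caught.
All randomness flows through R's global RNG; a run is reproduced
bit-for-bit by its seed, and serialized tissues carry the RNG state so
a resumed run continues identically.

The shortest-path search evaluates the chord length on a 720-point
angular grid over $[0, \pi)$ (vectorized over angles and edges)
followed by golden-section refinement in the winning bracket; against
an exhaustive $10^5$-angle search it is accurate to better than
$10^{-6}$ relative chord length. Chords that would pass within
$10^{-9}$ of an existing vertex are handled by rotating the direction
in $10^{-7}$-radian increments (bounded retries), since the division
construction assumes the plane cuts two walls. Non-convex (transiently
concave) cells are supported: the chord is the maximal inside segment
through the center.

## Initial states and the simulated protocols

A founder cell is a regular polygon (3–15 vertices) centered at the
origin, born stress-free with area 0.5 — half the division threshold —
so every founder starts below the trigger regardless of vertex count
(the sources describe the founders' shapes but not their size; this is
the package's choice). A library of initial states is grown from the
founders with the ShortestPath ⊗ COM rule; snapshots are captured once
the tissue first reaches the boundary-limited regime (150 cells) and
then at fixed intervals. The full-scale protocol is 13 founders × 25
snapshots = 325 states per rule; the package's tests and the acceptance
script use a reduced library (2–3 founders × 3–5 snapshots) and
continue each rule for 60 time units from every state — about eight
full tissue turnovers at steady state, enough for the continued rule's
own statistics to establish themselves — before measuring. Statistics
always exclude boundary cells (cells owning a wall with no neighbor on
the other side). These problem sizes were chosen so a complete
reproduction runs in minutes on a single core while keeping the
across-snapshot spread of each statistic well below the differences
between rules.

The oryzalin experiment — microtubule depolymerization that blocks
division while growth continues — is simulated by continuing a grown
tissue with division *and* boundary removal disabled (the removal
radius is left unused so the tracked cell population is preserved).
Topology is then frozen and the internal vertex angles relax toward the
ideal in which every $n$-gon is regular (angle $(n-2)\pi/n$); the
total-variation distance between the observed and ideal angle
histograms decreases to a residual plateau — frozen, mixed topology
cannot become exactly regular, so the distance does not reach zero.

## Design choices

* **Radial force form.** Only the proportionality of velocity to force
  and the existence of a radial forcing are fixed by the model
  description; the radial force's dependence on position is not. Both
  variants are implemented. The linear-in-$r$ form is the default
  because the constant-magnitude variant concentrates an ever-growing
  hoop tension in the rim as the vertex count grows, which squeezes
  boundary cells flat (eventually inverting their polygons) and makes
  the internal-angle distribution move *away* from the regular-polygon
  ideal when division is suppressed — the opposite of the oryzalin
  phenomenology the model is meant to capture. With the linear form the
  rim is under radial tension, no cell ever collapses, and the angle
  distribution converges cleanly, while the steady-state topology
  statistics and per-rule cell counts are unchanged.
* **Removal criterion.** "Outside the radius" is judged by the cell
  centroid: smooth, orientation-free, and independent of wall
  discretization.
* **Division order and cadence.** Over-threshold cells divide in
  ascending index order at every event check; several cells may divide
  after the same step. Division of an aborted cell (short cut wall) is
  simply re-attempted at later checks.
* **Deviation measure.** The comparison of a neighbor distribution with
  a reference defaults to the sum of squared fraction differences over
  the union of observed classes; L1 and chi-squared variants are
  selectable, and the metric used is recorded in report metadata. The
  rule *ranking* is the robust content of this statistic.
* **Reference distribution.** The experimental *Arabidopsis* 110-cell
  neighbor distribution is not publicly deposited; only its standard
  deviation (0.90) and skewness (0.53) are. The shipped default
  (`reference_distribution()`) is a clearly-labelled synthetic
  stand-in: a hexagon-dominated distribution on 4–9 neighbors
  constructed to match those two moments. Supply your own two-column
  table (`read_reference_distribution()`) for real comparisons.
* **Lewis' law reference.** The classical line $\bar A_n = (n-2)/4$
  (slope 1/4 after normalizing mean cell area to 1) is used as the
  reference the fitted slopes are compared against.
* **Error bars.** Across-snapshot spreads are sample standard
  deviations.
* **Angle histograms** default to 36 bins over $(0°, 180°]$; reflex
  angles (rare, transient) are clamped into the last bin.

## What the generator does and does not emulate

The synthetic tissues reproduce the mechanisms the model is about:
mechanics-coupled growth, threshold-triggered division under the
chosen rule, and boundary turnover. They do not emulate curved cell
walls (all walls are straight segments), anisotropic growth fields,
cell death, or the three-dimensional curvature of a real meristem; and
the division trigger is a sharp area threshold rather than a stochastic
cell-cycle model, which bounds cell areas in $(0.5, 1]$ and slightly
narrows the area distribution relative to real tissue — visible as
Lewis-law slopes below the classical 1/4. Passing tests therefore
demonstrate internal consistency of the model and reproduction of the
published tissue-scale statistics, not agreement with any particular
imaging dataset.

## Known limitations

* The ~10–15% high neighbor-number spread of the StrainPerpendicular ⊗
  COM rule relative to its published value persists under every
  variant we probed (signed vs clipped strain; the degenerate
  parallel-to-strain reading); the residual difference presumably lies
  in an unrecoverable detail of the original strain bookkeeping.
* Long no-division runs dilate the tissue exponentially under the
  linear radial force; coordinates remain well within double range over
  the relaxation horizons used (≤ 60 time units) but arbitrarily long
  oryzalin runs should use the constant variant or rescale.
* The simulator is single-threaded R; a ~220-cell steady-state tissue
  advances at roughly 5–10 simulated time units per wall-clock second.
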