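---
title: "Subcellular planar polarity from Dachsous/Fat bridges: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subcellular planar polarity from Dachsous/Fat bridges: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conduitpcp)
```

## The biological problem

Planar cell polarity (PCP) is usually described as a property of whole
cells. In the larval ventral epidermis of *Drosophila*, however, single
cells can carry membrane subdomains of *opposite* polarity: an "atypical"
cell that has slipped between two rows makes denticles that point forwards
in one part of the cell and backwards in another. The explanatory model is
that the Dachsous/Fat bridge system is read out *locally*: oriented
intracellular conduits link facing patches of the anterior and posterior
membrane of one cell, and each patch pair compares its own bridge
composition independently. This package turns that verbal model into an
executable one and checks its predictions — the wild-type row pattern,
multipolar atypical cells, *ds⁻ ft⁻* indeterminacy, clone repolarisation,
and the ambiguity of cells flanking tendon-row gaps — together with an
exact reproduction of the published contingency statistics.

## Model pipeline

A run (`run_scenario()`) is a deterministic chain with one random stage at
the very end (denticle orientation draws in unpolarized domains):

tissue → expression/activities → genotype → bridge relaxation → conduits →
calls → denticles → statistics.

### Synthetic tissue

`build_segment_map()` generates a hemisegment as an aligned rectangular
lattice; one segment is the row stack P, 0, 1, T1, 2, 3, 4, T2, 5, 6 along
the anterior–posterior (x) axis, with configurable columns along the
mediolateral (y) axis. Cells default to 30 µm × 30 µm, the size of
third-stage epidermal cells. Cell outlines are simple counter-clockwise
rectilinear polygons; shared boundaries are discretised into sub-segments of
at most `seg_len` (default 2 µm, at least two per contact), each tagged
anterior-facing, posterior-facing or lateral for either cell.

Choices worth stating:

* **Aligned bricks.** Real cell packing is brick-like with staggering, but a
  mediolateral stagger only adds extra *same-row* neighbours along the A–P
  axis and therefore cannot change any polarity call; the aligned grid keeps
  the geometry and the interface bookkeeping transparent.
* **Trailing P row.** Scenario maps append the anterior P row of the next
  segment after row 6 (`trailing_p = TRUE`), so that row 6 compares row 5
  against a real posterior neighbour instead of a map edge. Without it the
  posterior-most row is structurally unpolarizable.
* **Atypical cells** are realised by giving one cell a rectangular
  promontory that invades the neighbouring column: anterior-depth for row 4
  (so the reshaped cell's posterior membrane abuts both T2 and a normal
  row 4 cell), posterior-depth for rows 2 and 3. Promontory height (10 µm)
  and depth (half a cell) are parameters; the mediolateral span of real
  atypical cells is not documented, so it is exposed rather than fixed.
* **Tendon gaps** remove tendon cells and let the abutting posterior
  denticulate cell (row 2 for T1, row 5 for T2) expand into the breach, so
  the filler comes to lie between rows 1 and 3, or rows 4 and 6 — pairs
  with near-identical Ds activity.
* **Clones** (`mark_clone()`) flag a connected set of 1–5 non-tendon cells;
  the default size distribution is uniform on 1–5, the observed range for
  clones induced at the blastoderm stage. Sizes above 5 require an explicit
  override.

### Expression landscape and activities

Only *orderings* of Ds activity are documented, never numbers: tendon rows
are far lowest; row 3 lies between T2 and row 4; fj is highest in tendon
cells and graded from row 2 (high) to row 4 (low). The defaults
(`default_expression_params()`, arbitrary units) realise these with
Fj-modulated activities

\[ \mathrm{ds_{act}} = \frac{\mathrm{ds}}{1+\alpha\,\mathrm{fj}}, \qquad
   \mathrm{ft_{act}} = \mathrm{ft}\,(1+\beta\,\mathrm{fj}), \qquad
   \alpha=\beta=1, \]

giving Ds activities P 0.7, row0 0.8, row1 0.6, T1 0.1, row2 0.45,
row3 0.6, row4 0.8, T2 0.1, row5 0.6, row6 0.8. Two structural properties
of these numbers matter more than their values:

* rows 1 and 3, and rows 4 and 6, have *equal* Ds activity — this is what
  deprives a tendon-gap filler cell of any directional cue;
* the landscape is near mirror-symmetric about each tendon row out to
  second neighbours (e.g. fj(row 0) = fj(row 4), fj(P) ≈ fj(row 3)), for
  the same reason. fj of the rows the literature does not constrain (P,
  row 0, row 5) was chosen once to complete this symmetry; fj(P) = 0.2
  balances the row-6 call margin (which shrinks as fj(P) grows) against the
  residual asymmetry felt by a T2-gap filler.

The rational form of the Fj modulation is a boundedness/monotonicity choice;
only the direction of Fj's action is documented. The test suite asserts the
inequalities, not the numbers, and everything is overridable per run.

A within-cell expression gradient (the sloped per-cell profiles of the
transect cartoons) is implemented as anterior/posterior endpoint values
interpolated halfway towards the abutting rows (`gradient = TRUE` in
`assign_expression()`; `initialise_bonds()` then loads anterior-facing
segments with the anterior-endpoint density). The shipped scenarios run
with a *uniform* within-cell profile: endpoint interpolation towards unlike
neighbours makes a cell's presented protein depend on second-neighbour
identity, which measurably polarises the tendon-gap fillers that the
observations report as directionless. The flag keeps the sloped variant
available for exploration.

Genotypes: `ds_null`/`ft_null` zero the respective pools ("bridges cannot
form without either protein"); `ectods_clone` multiplies Ds activity by
K = 5, enough to dominate every neighbour.

### Bridge relaxation

Each cell owns Ds and Ft pools (mean activity × perimeter). Free protein
lives on boundary segments as per-µm densities and evolves by a synchronous,
deterministic two-step iteration (`relax_bonds()`):

1. **Bind/unbind.** On every interior segment the two bridge species relax
   towards mass action, `Δb = η (k_b φ_{ds} φ_{ft} − k_u b)`, damped by
   η = 0.4 and capped at half the limiting free pool per step so densities
   stay non-negative.
2. **Shuttle.** Each cell redistributes a fraction σ = 0.45 of each free
   protein over its own segments with weight
   `L · (1 + draw · φ_facing_partner)`: uniform over the membrane at
   `draw = 0`, biased towards segments whose facing membrane presents more
   unbound partner otherwise. This is the "drawing" step that lets a low-Ds
   cell (presenting unbound Ft) attract the neighbour's Ds and thereby
   propagates polarity between cells.

The weight's uniform baseline is essential: with a pure
proportional-to-partner rule a tiny pool (a tendon cell's Ds) concentrates
onto single segments at arbitrarily high local density and the fixed point
inverts the row-4 comparison, besides the iteration limit-cycling. Defaults
`k_b = 0.1, k_u = 1` put the model in a weak-binding regime in which bridge
composition tracks the *local* product of the two cells' activities; at
`k_b ≈ 1` network-wide depletion couples distant activity differences into
every comparison and polarises the gap-filler cells. `draw = 0.25` keeps
the propagation bias second-order relative to direct activity differences.

Iteration stops when the largest bond-density change falls below
`tol = 1e-10` (typically 60–150 iterations on a 55-cell map; the cap is
10 000, and non-convergence is a flagged warning, not an error). Per-cell
conservation — own free protein plus own protein in bridges equals the
pool — holds to ≤ 1e-8 at every step and is asserted in the tests, as is
agreement (≤ 1e-8) with an independently coded brute-force iteration on
small systems, mirror antisymmetry, and monotonicity of conduit scores in
the posterior neighbour's Ds.

### Conduits and calls

`build_conduits()` slices every non-tendon cell into mediolateral bands of
`band_width = 5` µm — six conduits across a 30 µm cell, so even a small
atypical promontory owns at least one — and pairs each band's
anterior-facing and posterior-facing membrane segments; a band missing
either side (map edge) yields no conduit. The conduit score is the
difference in the **own-Ft share of bridges** between the posterior and
anterior subregion (length-weighted; a bridge-free membrane contributes the
uninformative share ½). The share-based score lives on an absolute
composition scale in [−1, 1], is antisymmetric under exchanging the two
sides, and is exactly zero in bond-free tissue. It was preferred to a raw
own-Ft density difference because mass-action binding compresses absolute
free-density differences network-wide: the atypical promontory's density
difference is under 1 % of the map maximum while its composition difference
(own-Ft share 0.47 vs 0.41) is robust — and composition is also the
language of the bridge-majority cartoons, which the relaxed state
reproduces (Ds-majority on the row-4 side of T2|row4, Ds-majority on the
row-3 side of row2|row3, near-parity at row3|row4).

Calls use a threshold θ = 0.02 on that scale: membrane pairs whose bridge
compositions differ by two points or less carry no usable cue and are
`unpolarized`. In the shipped scenarios genuinely polarised subdomains
score |s| ≥ 0.04 and ambiguous ones (gap fillers, bond-free tissue)
|s| ≤ 0.011, so the calls are insensitive to θ over a factor of ~2 either
way. A relative variant (θ as a fraction of the map's maximum score) is
available via `theta = NULL`.

Cell classification: multipolar if anterior and posterior calls coexist;
unpolarized if all calls are (or no conduit exists); else unipolar. Clone
cells are forced to `unpolarized` by default
(`force_clone_unpolarized = TRUE`): their lack of preferred polarity is
thought to reflect saturated, direction-free bridge occupancy, a mechanism
the data only conjecture, so the package states it as a classification rule
rather than pretending the relaxation derives it.

`place_denticles()` puts denticles of polarized conduits adjacent to the
membrane the call points towards, inheriting its orientation; unpolarized
conduits place them centrally with orientation drawn uniformly — hence in
*ds⁻ ft⁻* tissue every orientation is an independent fair coin. One seeded
stream per run, consumed in cell-id order, makes outputs byte-reproducible.

### Statistics

`classify_denticle_domain()` follows the scoring protocol for atypical
cells: a denticle is classed by the cell its subdomain abuts on the
analysis side (posterior for row 4 atypicals, anterior for row 2) — tendon,
non-tendon, or intermediate when the labels are mixed or absent. Note the
class is geometric, not derived from the polarity call: in the mutant the
domains remain classifiable even though every call is unpolarized, which is
exactly what makes the independence test possible. `build_table()`
implements the published conventions for ambiguous denticles: allocate each
intermediate denticle to the table cell that maximises (favour-null) or
minimises (disfavour-null) the exact-test p-value, or drop them.

`fisher_exact()` is written from first principles: enumerate all 2×2 tables
with the observed margins, sum hypergeometric point probabilities not
exceeding the observed one — the point-probability two-sided convention,
chosen because it reproduces the printed 0.6135 and 0.7104 (other two-sided
conventions exist and do not). Probabilities use log-space factorials with
a relative tie tolerance of 1e-7; degenerate margins return p = 1.
`fisher_exact_rational()` is the independent oracle: numerators
`choose(r1,a)·choose(r2,c1−a)` built exactly from prime factorisations on a
tiny base-10⁴ big-integer, so extremeness comparisons and the summation are
exact, with one floating division at the end. The suite checks the two
agree to 1e-12 exhaustively for small totals and on random margins up to
total 60.

## Scenarios and problem sizes

The shipped scenarios run on one segment of five columns (55 cells with the
trailing P row, ~1 400 interface segments, ~210 conduits); the *ds⁻ ft⁻*
scenario uses seven columns with three atypical row 4 cells and three
denticles per conduit (900 denticles per run) so each seeded run yields an
atypical-cell contingency table of realistic size. A full run takes well
under a second; the entire analysis set and test suite run in about a
minute.

## What the generator does and does not emulate

The synthetic tissue reproduces the anatomy the analyses rely on: row
order, tendon rows one cell thick, cell scale, atypical two-row geometry,
tendon breaches, small clones. It does **not** emulate: irregular polygonal
cell outlines or size variability; cell rearrangement and identity changes
over developmental time (maps are static, as are the analysed stages);
expression noise (activities are exact row functions, so wild-type calls
are deterministic); denticle number variation per cell; or any second PCP
system. Passing tests therefore show that the conduit readout of the bridge
model *suffices* to produce the observed qualitative behaviours under the
stated landscape — not that real tissue satisfies the model's quantitative
assumptions.

## Known limitations

* The activity landscape is an ordering-constrained invention; absolute
  scores have no units and only signs/orderings are meaningful.
* The relaxation's fixed point is unique in practice (deterministic
  synchronous updates from a fixed initial allocation) but no uniqueness
  proof is attempted.
* Clone-cell indeterminacy is imposed by classification, not derived.
* Propagation of repolarisation beyond cells directly contacting a clone
  (occasionally observed in vivo) depends on the shuttle bias `draw`; with
  the conservative default it is not asserted, only demonstrable with
  larger values.
* Lateral (mediolateral) membranes participate in binding but not in the
  polarity readout; only the A–P axis is analysed.
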