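---
title: "Quantifying beta-cell connectivity: contact graphs, pair distributions and stochastic rearrangement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying beta-cell connectivity: contact graphs, pair distributions and stochastic rearrangement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletgraph)
library(dplyr)
```

## The problem

Islets of Langerhans are micro-organs of the pancreas containing α, β and δ
endocrine cells. Insulin-secreting β cells do not act alone: gap-junction
coupled β-cell clusters synchronise their calcium oscillations and secrete
insulin in pulses, so the *topology* of β-β contacts — who touches whom — is
functionally meaningful, and it differs between control and type 2 diabetic
(T2D) islets. `isletgraph` turns per-cell coordinate tables (subject, islet,
cell, x, y, optionally z, cell type) into β-cell contact graphs and provides
two complementary views of that architecture:

* a **static** view — graph measures (mean degree, components per islet,
  cells per component) and radial pair distribution functions g(r); and
* a **stochastic** view — balanced vertex rearrangement processes whose
  parameters are constrained by requiring that the simulated graphs keep the
  observed measures (*measure-equilibria*).

Everything runs on tibbles and returns tibbles, so each stage composes with
ordinary dplyr pipelines. A synthetic islet generator makes the whole
pipeline testable at desk scale without any deposited cohort.

## Contact graphs: the neighborhood radius and the shadow rule

Cells are not points: a β cell has a radius of about 4 µm, so a near
neighbour can physically block ("shadow") contact with a farther cell that
lies behind it. The graph construction therefore has two ingredients:

1. a **neighborhood radius** (centre-to-centre, in µm): only pairs within it
   may share an edge; and
2. the **shadow rule**: for each focal cell, candidates within the radius are
   traversed in order of increasing distance, and a candidate is rejected when
   its direction from the focal cell lies within the angular shadow of an
   already accepted neighbour. A neighbour at distance *d* casts a shadow of
   half-angle `atan(cell_radius / d)` — wider for touching cells, vanishing
   with distance.

Numerical choices that the traversal leaves open are fixed as follows and are
deliberately boring:

* **Tie-break**: equidistant candidates are ordered by ascending cell id, so
  the construction is deterministic.
* **Boundary**: a candidate exactly on the shadow cone boundary is accepted
  (rejection requires a strictly smaller angle); a measure-zero choice that
  avoids silently deleting edges in constructed geometries.
* **Symmetrisation**: each cell produces a directed acceptance list; the
  default `"mutual"` keeps an edge only when both endpoints accept each other,
  since a physical contact is necessarily mutual. `"union"` is available for
  sensitivity analysis.
* **Who casts shadows**: only accepted neighbours. A rejected cell is
  considered occluded, and an occluded cell does not itself occlude.
* **3d**: the same rule generalises verbatim with the angle between direction
  vectors tested against the same `atan(cell_radius / d)` cone.

The default radius is 10 µm, inside the 8–13 µm band where the pair
distribution of islet cells is non-random (below); `measure_islets()` sweeps
radii so conclusions can be checked across the whole 5–16 µm range.

## Graph measures and their weighting

For each islet graph we compute the mean degree, the number of connected
components (split into *singular* — lone β cells — and *nonsingular* —
β-cell clusters) and the number of cells per component. Components come from
graph traversal (igraph); the test suite verifies them against an independent
transitive-closure oracle.

Aggregation over a group follows each measure's own normalisation:

* **degree** is averaged over *cells* (every cell of the group contributes
  one degree, equivalent to summing degrees over the whole dataset and
  dividing by the total cell count);
* **components per islet** is averaged over *islets*;
* **cells per component** is, by default, averaged over *components*
  (total cells / total components), with a per-islet mean available via
  `component_weighting = "per_islet"` since the choice is not forced by the
  definitions. Graphs with no nonsingular component contribute nothing (not
  zeros) to the cells-per-nonsingular-component average.

Islets are classified large/small at a 60 µm **effective diameter**: the
diameter of the circle with the islet's equivalent area. We define that area
as the convex hull of all endocrine cell centres (not only β cells) padded
outward by one 4 µm cell radius; degenerate islets (one cell, collinear
centres) fall back to the maximum pairwise extent plus one cell diameter.
Equivalent-circle definitions differ in their padding conventions, so printed
large/small splits from other implementations are not expected to be
bit-identical; the classifier is a single function and easy to swap.

Group contrasts use the two-sided Mann–Whitney test with a Bonferroni gate
(`p < 0.05 / n_tests`); degree contrasts across a radius sweep conventionally
use `n_tests = 32` and component contrasts 64.

## Pair distribution functions

For one cell type within one islet, with N cells in a bounding box of area A,

$$g(r)\,dr = \frac{A}{2\pi r N^2} \sum_i \sum_{j \ne i} \delta(r - r_{ij}),$$

and for two disjoint types the ordered pairs run a→b with normalisation
\(N_a N_b\). Under complete spatial randomness (CSR) g is identically 1; an
excess at short range is spatial aggregation. The δ-sum is realised as a
histogram over 1 µm bins spanning 0–50 µm (the bin width is not dictated by
the estimator; 1 µm resolves the 8–13 µm band while keeping per-bin counts
stable). Bins with no pairs contribute g = 0, keeping the estimate defined
everywhere; islets with fewer than two cells, or a degenerate bounding box,
return an absent-value estimate and are skipped by the averaging step, which
is an unweighted per-bin mean over contributing islets.

Two deliberate simplifications matter when reading the curves:

* the normalising area is the axis-aligned bounding box of the cells entering
  the estimate — a convention, not an estimate of islet shape; and
* **no edge correction** is applied, exactly as in the estimator above. This
  biases g low at distances comparable to the islet (or box) extent: for a
  square window of side L the deficit grows like \(4r/(\pi L)\), about 12% at
  r = 30 µm for L = 300 µm. The calibration tests account for this: CSR
  recovery of g ≈ 1 is checked per-bin where the bias is small and as a band
  average over 5–30 µm, and the low bias at large r is itself asserted as the
  expected behaviour of an uncorrected estimator.

Distribution differences (`pairdist_difference()`) integrate |g₁ − g₂| by the
rectangle rule, over the full 0–50 µm window and over the 8–13 µm contact
band.

## The balanced rearrangement process

The stochastic view asks: which random rearrangement processes *maintain* the
observed architecture? Each iteration deletes one vertex and adds one vertex
per islet (cell number is conserved by construction — these are theoretical
abstractions of cell rearrangements, not birth and death). Selection is
governed by relative-likelihood kernels

$$RL^+ = 0.5 + 0.5\tanh(x - rlp), \qquad RL^- = 0.5 - 0.5\tanh(x - rlp),$$

where x is the vertex's degree (degree-based models) or the size of its
component (component-based models) and rlp is the sigmoid midpoint. P (= RL⁺)
favours high-x vertices, M (= RL⁻) low-x ones; the two sum to one for every
x. A model is written `[dir_a][dir_d][rlp_a][rlp_d]`: MP01 adds next to
low-x parents indifferently (rlp_a = 0) and deletes preferentially from
large clusters (rlp_d = 1). Selection probabilities are the normalised
kernel values over vertices — the minimal completion of "relative"
likelihoods into a sampling rule — with a uniform fallback if every weight
underflows to zero.

Deletion is trivial; **addition is steric**. The new cell is placed at a
uniform random distance in 8–13 µm from its parent, at an angle drawn
uniformly from the directions *not* occupied by a neighbour of the parent
(the complement of the union of the neighbours' shadow intervals — the same
occlusion geometry as the graph construction). Crowding is then resolved by
a propagating wave: cells within `d_min` of the newcomer are pushed radially
outward from the parent until their clearance to the nearest already-fixed
("frozen") cell lies in `[d_min, 10]` µm, cells newly crowded by a move are
appended to the problem list, and the wave runs until no violation remains.
Because every processed cell freezes, the wave touches each cell at most
once and terminates; a cycle guard covers pathological inputs.

Further fixed points of the implementation:

* `d_min` is the minimal centre-to-centre distance observed in the islet,
  **capped at 8 µm** (two touching cells) — placement distances start at
  8 µm, so an observed minimum above that would make the parent–newcomer
  pair an unfixable violation; islets with fewer than two cells use the 8 µm
  fallback outright.
* The outward step is the smallest translation restoring `d_min` clearance
  to every frozen cell, plus a uniform draw over the admissible slack up to
  10 µm clearance — the wave specification fixes the target interval but not
  the step, and a uniform choice avoids directional bias.
* Order within an iteration is delete-then-add, and degrees/component sizes
  are recomputed after every move (so the addition kernel sees the
  post-deletion graph). Both are configurable decisions, not consequences of
  the model definition.
* Runs consume the R RNG sequentially over a fixed (islet, replicate) order:
  one `set.seed()` makes a whole sweep bit-reproducible. Per-islet
  independent streams would only matter for parallel execution, which is out
  of scope.
* The C++ core recomputes components by union–find; the R-level measures use
  igraph. The two routes are compared in the tests, so neither silently
  drifts.

## Measure-equilibria

For a family (PP, PM, MP, MM) swept over an rlp grid — degree-based models
use midpoints 0–7, component-based 1–5, matching the observed ranges of each
basis quantity — each (measure, rlp_a) curve of mean simulated-minus-observed
differences is interpolated by an ordinary least-squares quadratic in rlp_d,
and its real roots inside the sweep are the measure-equilibria. A quadratic
*fit* (not a 3-point interpolation) is used because curves carry 5–8 points;
on exact quadratic inputs the fit is an interpolation and roots are recovered
to 1e-9. Near-zero quadratic coefficients degrade to the linear root;
complex and out-of-range roots are discarded. The summary reports, per
measure, the root range over rlp_a and a grand mean over all roots of all
measures (root-average rather than mid-range average; with roots tightly
clustered the two differ negligibly, and the root average uses all the
information). Families with no in-range root anywhere are flagged as having
no equilibrium.

At full scale this analysis consumes hundreds of thousands of simulations.
The package reproduces the *sign structure* at desk scale: on a synthetic
cohort of 100 islets, with 20 replicates of 100 iterations per parameter
combination (about four minutes of CPU), component-based MP difference
curves change sign in rlp_d while MM curves never do — the qualitative
fingerprint of "deletion from large clusters, indifferent addition" being
the equilibrium-capable family. Numerical equilibrium values at this scale
are indicative only; they are not expected to match full-scale sweeps of a
deposited cohort.

## 2d sections versus 3d volumes

Histology yields 2d sections, but islets are 3d. `perturb_z()` jitters each
cell's z by a uniform draw in ±7.5 µm (half a 15 µm slice) under a global
4 µm minimum distance, rejecting and redrawing per cell (up to 1000 tries)
— a per-cell rejection rather than whole-volume re-jitter, which preserves
the accepted cells and always terminates. `slice_volume()` then cuts the
volume into 15 µm slabs at every slice start 0–14; slabs are half-open
`[lo, hi)` so the sectioning is a partition — no cell lost or counted twice,
for any slice start. `compare_2d_3d()` aligns 3d neighborhood-sphere
measures with per-slice-start 2d measures across radii; on synthetic
volumes the measure-versus-radius curves are strongly rank-correlated
between geometries, the desk-scale analogue of "2d sections are
qualitatively faithful".

## The synthetic generator

`generate_cohort()` exists so that every stage has realistic input without
any deposited data. It emulates exactly the features the analysis relies on:

* a **hard core** of 8 µm between cell centres (two touching 4 µm cells),
  enforced exactly by dart throwing (rejection sampling) — not approximately
  by a Gibbs process;
* **short-range aggregation**: cells scatter around cluster seeds with an
  8 µm Gaussian spread, which together with the hard core concentrates
  nearest-neighbour distances just above 8 µm and puts the β-β pair
  distribution peak inside 8–13 µm (the retry loop widens the spread as
  rejections accumulate, so locally saturated clusters spill outward instead
  of jamming);
* an **islet size mixture** — 32% large islets (25–90 cells) and 68% small
  (3–12 cells), matching the large/small islet ratio of control cohorts —
  spanning the <60 µm effective-diameter boundary; and
* **endocrine fractions** (α, β, δ) = (0.33, 0.56, 0.11), near control
  cohort composition (~56% β).

It does *not* attempt mantle/core type sorting, realistic islet outlines,
vasculature-driven anisotropy, or the heavy tail of very large islets
(hundreds of cells). Tests passing on synthetic cohorts therefore validate
the algorithms and their invariants — construction, counting, calibration,
conservation, sign structure — not any biological claim about real tissue.

## Degenerate inputs and failure modes

Coincident cell positions are a geometry error (the shadow angle is
undefined at zero distance). A parent with no free placement angle triggers
reselection of a different parent, and an islet where no parent has a free
angle is a simulation error. Dart-throwing failure (density infeasible
within the retry budget) errors with a suggestion to reduce the cell count.
Tied Mann–Whitney samples warn and return p = 1. All-zero difference curves
are flagged degenerate and contribute no roots.

## Problem sizes used by the test suite

The suite runs entirely on generated data at sizes chosen to exercise every
code path while keeping a full run around five minutes: oracle equivalence
on 200 random ≤12-point scatters plus 60 component checks on ≤15-vertex
graphs; CSR calibration with 50 replicates of 500 points; a 200-islet
conservation/steric audit over 100 iterations; and the 100-islet, 20×100
MP-versus-MM sign-structure sweep described above.
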