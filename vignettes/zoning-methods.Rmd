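---
title: "Zoning protected ecological areas with a discrete bee colony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zoning protected ecological areas with a discrete bee colony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonebee)
```

## The zoning model

Regional planning authorities that delimit protected ecological areas face a
combinatorial allocation problem: out of all raster cells eligible for
protection ("configurable" cells), exactly `Q` must be selected — the quota
usually comes from a planning mandate — and the selected pattern should sit
on ecologically valuable land, avoid land that is attractive for urban
development, and hold together spatially rather than fragment into scattered
pixels.

zonebee encodes a candidate scheme as a binary raster `x` with
`sum(x) = Q`, protected cells only on configurable positions, and scores it
with three normalized criteria:

* **Ecological suitability** `sum(Eco_i * x_i) / Q` — the mean suitability
  of protected cells (maximized). `Eco` is a `[0, 1]` layer, typically a
  weighted multi-criteria combination of vegetation, terrain, water, soil
  and land-use factors (see `weighted_linear_summation()`).
* **Development potential** `sum(Dev_i * x_i) / Q` — the mean urban
  development potential of protected cells (minimized). Protecting land
  under development pressure both blocks growth and exposes the reserve to
  adjacent disturbance, so it enters the combined objective as
  `1 - Development`.
* **Compactness** `sum(Com_i * x_i) / Q`, where `Com_i` is the
  *neighborhood density* of cell `i`: the fraction of protected cells among
  the configurable cells in the `n x n` window centered on `i`. Site
  criteria are properties of each cell alone; compactness is a property of
  the pattern, and is what distinguishes this model from per-cell ranking.

The scalar objective is the weighted sum

```
fitness(x) = w1 * Ecological + w2 * (1 - Development) + w3 * Compactness
```

with non-negative weights summing to one, so fitness always lies in
`[0, 1]`. With `w3 = 0` the problem is separable and the exact optimum is
the top-`Q` cells by the *site score*
`s_i = (w1 * Eco_i + w2 * (1 - Dev_i)) / (w1 + w2)` — this is exactly what
the `density_slice()` baseline returns, and it is the oracle several tests
lean on. With `w3 > 0` the problem becomes a hard spatial optimization (the
value of protecting a cell depends on which neighbors are protected), which
is why a metaheuristic is used.

### Window convention

The compactness window is an `n x n` block centered on the cell, *including*
the cell itself, truncated (not padded) at raster borders: border cells are
judged against the neighbors they actually have rather than against
invented off-grid cells. A window with no configurable cells scores 0; this
cannot happen for a protected cell (a protected cell is configurable and
inside its own window) but keeps the function total. The default `n = 3` is
the smallest window that measures adjacency; it is exposed as
`abc_control(window = ...)` because coarser rasters may warrant 5 or 7.
Note that truncation gives border cells smaller denominators, so a block
pushed against a border is slightly *more* compact by this measure than the
same block mid-grid; with interior optima (as on the validation surface)
this has no practical effect.

## The optimizer

`zone_abc()` is a discrete artificial bee colony. The colony keeps `SN`
candidate solutions ("food sources"); each cycle applies four phases:

1. **Employed phase.** Each source `u_j` proposes one neighbor built from a
   randomly chosen other source `u_k` and keeps it only if strictly better
   (greedy retention).
2. **Onlooker phase.** Selection probabilities
   `p_j = fitness_j / sum(fitness)` are computed once per cycle; `SN`
   onlookers each follow a roulette-selected source and apply the same
   propose-and-keep step. Good sources therefore receive more search
   effort.
3. **Local search.** The cycle-best source is polished by the swap search
   (below).
4. **Scout phase.** A source that has not strictly improved for `limit`
   consecutive cycles is abandoned and re-seeded with a fresh
   mixed-initialization solution, which is how the colony escapes exhausted
   basins.

The global best over all cycles is the result; its per-cycle trace is
non-decreasing by construction.

### Mixed initialization

Purely random starting populations are diverse but poor; purely greedy ones
are good but identical. Each initial source is therefore drawn by the
*pseudo-random* method with probability `init_pseudo_prob` (default 0.5) and
by the *complete-random* method otherwise. The pseudo-random method places
`floor(init_best_fraction * Q)` cells greedily at the top site scores
(default fraction 0.5) and fills the rest by roulette draws proportional to
`s_i`; the complete-random method samples `Q` configurable cells uniformly.
The two mixing probabilities are exposed because the right balance depends
on how informative the site layers are; the defaults treat quality and
diversity symmetrically.

### Replace-and-alter neighbors

A neighbor of `u_j` copies a region from `u_k`, then restores the quota by
toggling cells outside the region:

* Region strategy **R1** draws a rectangle with uniform position and side
  lengths uniform on `1..ceiling(dim/4)`, clipped at the border — large
  enough to transplant coherent patches, small enough not to clone `u_k`.
* Region strategy **R2** collects the `m` protected cells of `u_j` with the
  *worst* site scores, `m` uniform on `1..ceiling(0.1 * Q)`, so weak cells
  are preferentially exposed to replacement.
* Alteration **A1** performs each balancing toggle at the eligible outside
  cell with the best exact incremental objective change (ties to the lowest
  row-major position); **A2** toggles a uniformly random eligible cell.
  Only the direction that restores `sum(x) = Q` is considered — the
  alteration exists for numerical balance, not as a second search move.

Strategies are mixed 50/50 by default (`p_rect`, `p_best_alter`). If no
eligible cell remains (conceivable only when the region covers nearly all
configurable cells) the move is abandoned and `u_j` is kept; the event is
counted in `degenerate_moves`.

### Swap local search

The swap operation exchanges one protected and one unprotected cell. A full
scan of all `Q * (N - Q)` pairs per exchange is quadratic and unnecessary;
zonebee selects the pair as *best removal first, then best addition given
that removal*, each by exact incremental delta, and accepts only if the
joint delta is strictly positive (a `1e-12` guard suppresses
floating-point noise). The number of attempted exchanges per cycle is drawn
uniformly from `swap_range`, default `(20, 40)`; the search stops early at
the first non-improving exchange, so fitness never decreases. Greedy
pair selection can in principle miss an improving pair a full pair scan
would find; in practice the neighbor operator supplies the coarse moves and
the swap converges exactly in the separable case (a property the tests
assert).

### Incremental evaluation

All inner-loop evaluation is incremental. For the current solution the
package maintains, per cell, the number of protected cells in its window
and the sum of `1/D_j` (window configurable counts) over protected window
members. A single toggle then updates `O(n^2)` cells and the exact fitness
change of any candidate toggle is `O(1)`, making the A1 scan and the swap
scan `O(N)` rather than `O(N * n^2)` re-evaluations. `fitness_delta()`
exposes this machinery, and the test suite holds it to within `1e-9` of
full recomputation along random toggle walks (double-precision drift over
the bookkeeping is orders of magnitude below that).

### Reproducibility

Every stochastic choice — initialization, neighbor selection, region and
strategy draws, roulette, swap counts, scout re-seeds — flows from R's
global RNG in a fixed documented order, and the compiled layer draws
nothing itself, so `zone_abc(..., seed = s)` is bit-reproducible.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `SN` | 12 | food sources; matches the regional-application setting used throughout |
| `limit` | 150 | cycles without strict improvement before a scout restart |
| `mcn` | 1000 | cycles; 200 suffice on the validation surface, ~500+ on harder regional layers |
| `window` | 3 | compactness neighborhood side |
| `init_pseudo_prob` | 0.5 | share of pseudo-random initial sources |
| `init_best_fraction` | 0.5 | greedy share inside the pseudo-random initializer |
| `swap_range` | (20, 40) | exchanges attempted per local search |
| `p_rect`, `p_best_alter` | 0.5 | strategy mixing probabilities |
| weights | task-specific | e.g. 0.34/0.33/0.33 for an even three-way trade-off |

`Q` is not a tuning parameter: it is the planning quota and every solution
holds it exactly at all times.

## The synthetic validation landscape

`multipeak_surface()` builds the landscape used to verify optimum recovery
without any external data: a 200 x 200 surface that is the normalized sum
of five Gaussian bumps — a central peak (amplitude 1, sigma 20 cells) and
four corner peaks (amplitude 0.5, sigma 10). The development layer is zero
(the two site criteria are folded into one surface) and all cells are
configurable. The geometry is calibrated so that the known optimum of the
site score is the central disk: the surface value at radius 20
(`exp(-0.5) = 0.607` of the peak) exceeds the corner amplitude 0.5, so the
top 1250 cells form the radius-20 disk at the center (about `pi * 20^2 =
1257` cells); the tests assert a Jaccard overlap of at least 0.95 between
the top-1250 level set and the disk. Because the center peak is radially
monotone, any sigma satisfying that inequality yields the same level-set
geometry, so the sigma is fixed rather than solved per-generation. The
corner bumps are genuine local optima — a colony seeded randomly will
transiently gather protected cells there — but their values stay below the
disk rim, so the global optimum is unambiguous.

With `Q = 1250`, weights `0.67/0/0.33` and 200 cycles, the optimizer should
place all but a fraction of a percent of the quota inside the disk; the
handful of boundary cells that land just outside reflect the discretization
of a continuous disk, not a search failure. This experiment — median over
five seeds — is what `scripts/acceptance.R` reproduces.

What the synthetic landscape does *not* emulate: real suitability maps have
anisotropic ridges, plateaus and nodata holes, correlated eco/dev layers,
and configurability constraints from ascertained resources. Passing the
validation therefore demonstrates correct optimization of the stated
objective and the ability to escape symmetric local optima, not that any
particular real-world zoning is ecologically right.

## Numerical and design choices

* **Site score definition.** The pattern-free score
  `s_i = (w1 * Eco + w2 * (1 - Dev)) / (w1 + w2)` is used wherever a
  per-cell quality is needed (pseudo-random init, R2 regions, density
  slicing). It is the objective restricted to its separable part, which
  makes density slicing exactly optimal at `w3 = 0` and keeps all
  quality notions consistent. When `w1 + w2 = 0` the score degenerates to a
  constant and the roulette fallbacks take over.
* **Tie-breaking.** All deterministic argmax/top-`Q` selections break ties
  at the lowest row-major (row, then column) position, so runs are
  reproducible even on degenerate (constant) layers.
* **Quota normalization during repair.** Objectives divide by the fixed
  quota `Q`, not the current protected count, so off-quota intermediate
  states during replace-and-alter evaluate consistently and deltas compose.
* **Trial bookkeeping.** A source's trial counter is updated once per
  cycle: reset on any strict improvement in that cycle (employed, onlooker
  or local-search), incremented otherwise. Strictness matters: on flat
  regions of the objective, accepting equal-fitness moves would reset
  counters and starve the scout phase.
* **Scout re-seeding** reuses the mixed initializer rather than only the
  uniform one, so restarts inherit the same quality/diversity trade-off as
  the initial population.
* **Onlooker count** equals `SN` (one follow per onlooker), the standard
  colony convention, and probabilities are computed once per cycle.
* **Degenerate inputs.** Layers outside `[0, 1]` are a hard load error
  (silent clamping hides preprocessing bugs); `Q` larger than the
  configurable count is a configuration error raised before any iteration;
  an all-zero fitness vector makes the roulette uniform.
* **Coordinates** are 1-based `(row, col)` with row 1 at the top, matching
  R matrix indexing; raster files are written top row first.

## Problem sizes used in the tests

The bundled tests run entirely on generated data: enumeration oracles on
4 x 4 grids (`choose(16, 3) = 560` subsets), invariant sweeps on 8 x 8
random instances (hundreds of neighbor moves and a 1,000-step toggle walk),
the full 200 x 200 validation experiment at five seeds and 200 cycles, and
fifty paired-seed initialization trials. These sizes keep the whole suite
in the low minutes on one core while still exercising every phase of the
algorithm at the study scale.

## Limitations

* Land units are single cells; aggregating cells into polygons or
  enforcing must-include resources is only representable by preprocessing
  the configurable mask.
* The weighted-sum scalarization yields one solution per weight set, not a
  Pareto front; exploring trade-offs means re-running with different
  weights.
* Raster I/O is plain-text ESRI ASCII grid; GeoTIFF inputs must be
  converted upstream.
* Compactness is a local window density; it does not measure global
  contiguity, so a solution of a few large blobs can score similarly to one
  big patch with the same boundary share.

## A worked miniature

```{r}
set.seed(1)
g <- random_instance(12, 12, blocked_fraction = 0.1)
w <- zoning_weights(0.34, 0.33, 0.33)
fit <- zone_abc(g, Q = 20, weights = w,
                control = abc_control(SN = 6, mcn = 50, limit = 25),
                seed = 7)
fit
ds <- density_slice(g, 20, w)
evaluate_fitness(ds, g, w, 20)   # site-only baseline, same weights
```

The colony beats the baseline by trading a little site quality for
compactness — exactly the trade-off the third objective encodes.
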