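---
title: "Methods: effort-corrected endemism, phylodiversity and PA gap accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effort-corrected endemism, phylodiversity and PA gap accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gapscape` implements a protected-area (PA) gap analysis: given occurrence
records, PA and biome polygons, environmental rasters and phylogenies, it
asks what share of species, endemism, phylodiversity and phylogenetic
endemism the PA network fails to cover, and how that shortfall is
distributed over PA categories, biomes and designation epochs. This
vignette is the package's own account of the models, the tunable
parameters, the numerical choices, and what the synthetic-data tests do and
do not demonstrate.

## Geometry and units

All computation is planar, in kilometres. Polygons are plain vertex
matrices; areas are shoelace areas; point-in-polygon queries go through
`mgcv::in.out()`. Inputs in geographic coordinates must be projected before
entering the package — the degree-based "0.5° hexagon" of field practice is
represented by a configurable hexagon diameter whose default, 55 km, is the
approximate ground distance of 0.5°. Working on a planar synthetic extent
preserves every ratio the indices depend on while avoiding projection
machinery.

The hexagonal grid (`hex_grid()`) uses flat-top hexagons with row-major,
stable cell ids. Because all cells are congruent, the tessellation is the
Voronoi diagram of the cell centres, so point membership is nearest-centre
lookup; boundary ties resolve deterministically to the lowest cell id. Grid
cells clipped by the extent keep their clipped area, which is what record
densities divide by.

## Sampling effort

Occurrence databases are survey-biased: collection concentrates near roads,
cities and research stations. The effort estimate at a record is the disc
count density — the number of records of any species within 50 km, divided
by the disc area. A species' effort is the mean over its records, normalized
by the best-sampled species, then clamped to the open interval
`(1e-5, 1 - 1e-5)`. The 50-km radius matches the neighbourhood
conventionally used for record-density kernels; the clamping margin equals
the smallest constant used by the correction itself (see below), and is
required because the correction is undefined at 0 or 1. The disc-count form
is the simplest estimator consistent with an "average kernel index" reading;
it is a design choice of this package, not a claim about any particular
historical implementation.

## Weighted endemism and the effort correction

Per species, `WE = 1/range_size` with range size the number of occupied
hexagons; a cell's WE is the sum over its species. Two conservation laws
follow and are asserted in the tests: each species contributes exactly 1
across its range, so the cell sums add up to the number of recorded
species; and any partition of cells partitions the WE mass exactly.

The corrected index combines three strictly-open-unit-interval terms,

$$\mathrm{cWE} = \frac{AB}{AB + (1-A)(1-C)},$$

with `A` the (clamped) WE, `B = A x effort`, and `C` a record-count term:
`C(1) = 1e-5`, `C(n >= 150) = 0.999`, linear in between — 150 records is
where record-frequency distributions in large compilations reach their
asymptote. The index is strictly increasing in each argument, so better
sampling never lowers a species' corrected endemism, and under saturated
effort and record counts the corrected ranking equals the raw WE ranking.
Whether the effort term should be species-level or cell-level is genuinely
open; the package uses the species-level mean over the species' own records
(each record contributes its 50-km neighbourhood), and aggregates corrected
values per cell by summing over the species present, mirroring the raw WE
aggregation.

## Phylogenetic dimensions

Supertrees are assembled from source trees by matrix representation with
parsimony: every non-root internal node becomes a binary character
(descendants 1, other taxa of that tree 0, absent taxa `?`); unresolved
polytomies contribute only their resolved nodes. The search is a parsimony
ratchet: NNI hill-climbing alternating between perturbed weights (a random
25% of characters upweighted to 2) and the original weights, starting from
neighbour-joining on MRP Hamming distances, keeping the best tree, 200
iterations by default. Settings are conventional and configurable; the
search is deterministic for a fixed seed, never returns a tree worse than
its start, and ends at an NNI-local optimum. Fitch scoring uses the
two-state majority rule at each node, which coincides with Fitch's set
operations on binary nodes and scores polytomies exactly for binary
characters. Because branch lengths from heterogeneous sources are not
comparable (and often absent), all branches are set to length 1.

Faith PD is the rooted variant: the branch length of the union of
root-to-tip paths, shared branches counted once. PWE assigns each branch a
range (the union of its descendant tips' cells) and spreads its length
uniformly over that range; summed over cells, every recorded branch
contributes exactly its length — the PWE conservation law asserted to
1e-9. "Share of lineages protected" is, headline, the share of recorded
branch *length* whose range touches a PA cell (consistent with how PD and
PWE weight lineages); the branch-count share is reported alongside because
the length/count distinction matters for readers comparing against other
analyses. Branches with no recorded descendant are excluded from both
numerator and denominator.

## Species distribution models and representativeness

Environmental layers are reduced to the first four axes of a PCA on the
correlation matrix (standardized variables). Four classic suitability
models are fitted per species on those axes: Bioclim (percentile envelope,
`min_a(1 - 2|F_a(x) - 0.5|)` with a midpoint ECDF so training extremes stay
strictly positive while values outside the envelope score exactly 0),
Domain (best Gower similarity to any training point), Mahalanobis
(`exp(-D^2/2)` to the training mean and covariance; a singular covariance is
an explicit failure) and a logistic GLM against pseudo-absences. Maxent,
boosted trees and SVMs are deliberately out of scope: they are off-the-shelf
methods whose re-implementation would add no fidelity, and the four in-scope
algorithms exercise the same ensemble logic.

The binary range uses the lowest training-point suitability as threshold —
the most conservative choice grounded purely in the empirical records — so
training omission is zero by construction (asserted for every fitted
species). Model adequacy is screened by a rank-based AUC (ties credited
half) against pseudo-absences; fits with AUC ≤ 0.7 are flagged and excluded
from summaries. Pseudo-absence protocol (not fixed by field convention,
hence a recorded choice): uniform background cells, ten per presence,
excluding cells within one cell width of a presence, drawn with the run's
seed. Species with fewer than 15 usable records are skipped with a logged
reason rather than fitted badly. Representativeness is the percentage of
the binary range — restricted to remaining native vegetation when a mask is
supplied — whose cells fall inside PAs; an empty masked range is flagged
`NA`, not silently zero.

## Protection accounting

A record is protected if it falls inside a PA polygon; a species if any of
its records is. Double-designated land resolves by the precedence
strict > sustainable > indigenous — conservative in the sense of crediting
the strictest regime; the order is a configuration point of
`classify_protection()`. Cell-valued dimensions (WE, corrected WE, PWE)
partition over PA-overlapping versus other cells; overlap is tested at the
cell centroid, the six hexagon vertices and the PA vertices, which captures
every overlap of non-negligible area when hexagons are smaller than the PA
features (the only missed configuration, an edge-crossing sliver touching
neither kind of vertex, has negligible measure for the polygon sizes the
generator produces). Mixing record-level accounting for species with
cell-level accounting for the indices is intentional: the former matches
how occurrence data enter PA registries, the latter is forced by the
cell-valued definition of the indices, and both are reported explicitly.

Record densities inside versus outside PAs are compared by Kruskal–Wallis
tests with hexagonal cells as sampling units (overall and per biome), and
cell endemism by a Mann–Whitney test, both through the standard `stats`
implementations; all-tied inputs return H = 0, p = 1 rather than NaN. The
per-PA table reports record counts, densities with log-decade legend
classes (`[0]`, `(0,0.01]`, ..., `(10,130+]` records/km² — the interior
breaks are shown only in map legends in field practice, so log decades are
assumed and configurable), and the share of each PA within 1 km of any
record (the mode of maximum collection distances), computed by
deterministic grid sampling of the PA at a resolution fine relative to the
buffer radius.

Accumulation curves add PAs in designation order and track the cumulative
protected share of all four dimensions. Per-epoch slopes are reported "in
degrees", which is meaningless without declared axis scaling, so the scaling
is explicit and configurable: within each epoch the year is rescaled to the
epoch span and the cumulative value to a fraction of the all-PA endpoint;
the slope of the linear fit on those axes is converted by `atan`. The
epochs default to the designation phases 1903–1950, 1951–1980, 1981–1990,
1991–2000, 2001–2016, and the curve endpoint is asserted to equal the
static accounting.

## The synthetic generator: what it emulates, and what passing tests show

`generate_world()` draws, from a single seed (byte-identical reruns):
vertical biome strips with jittered widths; three PA categories
(default 8 each) as clipped regular polygons with designation years skewed
80% post-2000; species ranges as unions of 1–3 discs with log-normal radii;
heavy-tailed per-species record counts (rounded log-normal, median ~8, a
few species above 150 — the law is exposed as `rrecord_counts()` so tests
can compare realized counts against it); records drawn uniformly within the
range and thinned by an effort field of Gaussian hotspots over a uniform
floor; 21 spatially autocorrelated environmental layers (gradients plus
smoothed noise — species ranges being spatially compact, any smooth layer
set induces learnable niches without assigning them explicitly); and a
random unit-branch phylogeny over all species. Record years are carried for
schema completeness but no in-scope analysis consumes them; PA designation
years drive the temporal curves.

Two calibration scenarios have ground truth by construction.
`scenario_gap(target)` places a known fraction of species with ranges
strictly disjoint from every PA (placement failure raises a diagnostic
rather than silently missing the target) and anchors each remaining
species' first record at its range centre inside a PA. The anchor is
deliberate: a 1-record species whose range merely overlaps a PA would be
counted unprotected about half the time, and the scenario's purpose is a
fixture whose record-based truth is exact, not a naturalistic world.
`scenario_representativeness()` builds layers varying along x only (plus
small iid cell noise), species ranges as x-bands, and a single PA strip
covering an exact fraction of the grid rows, so any y-invariant predicted
range contains exactly that fraction — the defaults (80 presences per
species, noise SD 0.03) are chosen so the fitted ranges are dense enough
for that y-invariance to hold in practice for all four algorithms.

What the passing tests show: the indices obey their conservation laws; the
corrected index matches its closed form and monotonicity; the supertree
search attains the exhaustively verified parsimony optimum on 6-taxon
problems; known outside-fractions and PA-overlap fractions are recovered
within the stated bands. What they do not show: robustness to
georeferencing error, taxonomic synonymy, non-disc range shapes, or the
spatial structure of real road-network bias — none of which the generator
emulates. Real-data conclusions inherit the quality of the inputs.

## Problem sizes and numerical details

The test suite and the acceptance script run on deliberately modest sizes —
default worlds of 150 species (tests mostly 25–100), 24 PAs, ~540 hexagons,
80×80×21 environmental cells; supertree checks on 4–7 taxa where exhaustive
enumeration (105 six-taxon topologies; brute-force state enumeration for
Fitch) is feasible as an oracle. Effort computation is O(n²) in records and
comfortable into the tens of thousands. Other numerical choices collected
in one place: ε = 1e-5 clamping before the corrected index; disc-union
sampled areas by grid sampling (default ≤ ~40k probes, never coarser than
radius/5); hexagon boundary ties to the lowest id; NJ start and
first-best-neighbour moves make the ratchet deterministic under its seed;
GLM separation warnings are suppressed because extreme fitted probabilities
are harmless to thresholding and rank AUC; report JSON is serialized with
fixed options so identical configurations reproduce identical bytes.

## Limitations

Planar geometry only; no geodesic areas or CRS handling. Range size is hex
occupancy — no alpha hulls or EOO polygons. The three excluded SDM families
would need external adapters. The effort estimator is one defensible
formalization among several; conclusions sensitive to its exact form should
be checked against alternatives. Biome assignment of boundary-straddling
cells follows the cell centroid.
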