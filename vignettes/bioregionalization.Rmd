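---
title: "Methods: occurrence-based bioregionalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occurrence-based bioregionalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioregionize)
```

# The problem and the model

Marine invertebrate faunas are structured into biogeographical units —
bioregions, subdivided into bioprovinces — shaped by ocean currents,
climatic zonation and geological history. Given a table of georeferenced
occurrence records of a clade (here calibrated to the scale of living
brachiopods: roughly 400 species in 100 genera and 15,000 usable records
worldwide), the package delineates those units quantitatively rather than
by expert judgement alone. The underlying model is compositional: two
places belong to the same unit to the extent that they share species.
All inference is therefore carried by binary cell × taxon incidence
matrices and Jaccard dissimilarities between the cell species sets,
`d(A,B) = 1 − |A∩B| / |A∪B|`. No abundance weighting is attempted: the
occurrence counts behind the incidences are too heterogeneous across
literature sources for abundances to be comparable, and they enter the
analysis only through rarefaction, as a sampling-effort proxy.

The pipeline is deliberately staged, and each stage is an exported
function with its own contract, so intermediate artifacts (cleaning logs,
incidence matrices, dendrograms, network layouts) can be inspected and
exported. `run_pipeline()` composes the stages and carries a manifest of
record counts so that conservation (`kept + rejected = input`, cell counts,
cluster counts) is checkable at every step.

# Cleaning rules

Raw compilations mix identification qualifiers into taxon name strings.
Records qualified `aff.`, `cf.` or `indet.` are rejected outright — an
uncertain identification cannot support a presence claim — while `sp.` and
`spp.` records are kept but demoted to genus level: they contribute to
genus richness G and to the genus incidence matrix, never to species
richness S, endemism E or the species incidence used for clustering.
Qualifier tokens are detected case-insensitively, with or without trailing
periods, and a synonym table (applied after qualifier stripping) maps
misspellings and superseded names to accepted binomials; accepted names
must be fixed points of the table, so reconciliation cannot chain.

Coordinates with |latitude| > 90° or |longitude| > 180° are rejected;
surviving longitudes are normalized to [−180, 180), so 180° and −180°
are the same meridian. Records whose coordinates were geocoded from a
place name are snapped to the nearest 0.5°, reflecting the precision such
geocoding can honestly claim. A land mask (point-in-polygon via
`mgcv::in.out()`) is available but off by default: occurrence databases
are marine here, and a mask is only as good as its polygons. Exact
duplicates (name + coordinates + source) are collapsed with a
multiplicity count rather than silently dropped, which keeps cleaning
idempotent: `clean(clean(X)) = clean(X)`.

# Gridding conventions

The analysis grid is the equal-angle 5° graticule (36 × 72 cells). Cells
are half-open, `[lower, upper)` on both axes, with latitude 90° folded
into the top row — this makes cell assignment total and unambiguous, a
convention the package fixes because boundary records must land
somewhere deterministic. Human-readable labels follow the
`"35°N130°E-30°N135°E"` convention (north-west corner, then south-east
corner); they are presentation only, and internal identifiers are
`r<row>c<col>` strings, because printed labels of this style are easy to
typo and should not be trusted as keys. Clustering is restricted to cells
with at least 7 species (a cell with exactly 7 survives): cells below
that carry too little compositional signal and would join clusters on one
or two shared widespread species.

# Rarefaction

Sampling completeness is assessed with individual-based (Hurlbert)
rarefaction, treating occurrence records as the individuals — the only
effort proxy a literature compilation offers. The expectation
`E[S_n] = Σ_i [1 − C(N−N_i, n)/C(N, n)]` is exact hypergeometric
arithmetic, evaluated with `lchoose` so totals of 10^5 records do not
overflow; the optional variance uses the standard pairwise hypergeometric
formula and is quadratic in the species count. Strata are the six 30°
climatic zones (polar, temperate, tropical, each hemisphere) or 5°
latitudinal bins. The asymptote diagnostic is the slope over the last 10%
of the n-range, flagged against a default threshold of 0.01 species per
additional occurrence; a one-point curve reports the flag as undefined
rather than guessing.

# Two-stage clustering

Stage one clusters the filtered cells; stage two clusters the resulting
cluster species pools and cuts at a fixed dissimilarity, condensing many
clusters into a few groupings. The agglomeration is a hand-rolled
Lance–Williams implementation rather than a call into an existing one for
two reasons: the tie-breaking rule must be fully specified for
cross-platform determinism (ties in the minimal merge distance are broken
by the lexicographically smallest pair of cluster indices, a cluster being
indexed by its smallest member leaf), and the test suite verifies the
implementation against a brute-force agglomerator that rescans all member
pairs at every step — a check that requires owning the code path. Average
linkage (UPGMA) is the default: it is the conventional partner for
ecological incidence data and produces monotone dendrograms (no
inversions, asserted in tests). Complete, single and Ward linkage are
available; `"ward"` follows the Ward.D2 convention, verified against both
`stats::hclust` and a coordinate-space minimum-variance oracle.

Cutting into K clusters removes the K−1 highest merges; labels are
assigned by first appearance along the dendrogram leaf order. Height cuts
keep merges at height ≤ the threshold (a merge exactly at the cut
survives), so cutting at the maximum merge height yields one cluster and
cutting below the minimum yields singletons.

The number of primary clusters is a judgement call that the package
supports but does not make: `select_k()` tabulates, for each candidate K,
the total within-cluster sum of squares (WSS, computed in incidence-vector
space against per-cluster centroid vectors — matching the centroid framing
of the elbow method) and the average silhouette width
(`s = (b − a)/max(a, b)`, singletons contributing 0, cross-checked against
the cluster package). The elbow is operationalized as the K maximizing the
second difference of WSS — a visual criterion needs an executable
definition for testing — and local silhouette maxima are flagged, but the
final K is the caller's. The pipeline default is K = 20 with a secondary
cut at dissimilarity 0.935 (Jaccard similarity 0.065), the operating point
used in global-scale work of this kind; both are plain arguments.

# Network verification

The groupings are cross-examined on a bipartite cluster–species network.
The layout is a ForceAtlas2-style iteration — linear edge attraction
scaled by weight^(edge weight influence), degree-mass repulsion scaled by
the `scaling` constant, central gravity, displacement-capped steps, and an
annealed adaptive speed so late-stage displacement shrinks monotonically;
iteration stops once mean displacement falls below the tolerance.
Coordinates are deterministic given the seed; a single node sits at the
origin, the gravity fixed point. The Barnes–Hut `approximation` (theta)
parameter is honoured through a coarse-grid aggregation that engages only
above a node-count threshold; the networks this package builds are far
smaller, and repulsion is computed exactly for them. Coordinates are not
expected to match any particular desktop tool's output — only relational
properties (within-block versus between-block distances, determinism,
convergence) are asserted, and no LinLog mode or overlap prevention is
implemented.

Because "the network shows the same picture" is not a testable statement,
the package adds a quantitative consensus statistic: the bipartite network
is projected onto its cluster nodes with shared-species Jaccard weights,
communities are detected by greedy modularity maximization
(`igraph::cluster_fast_greedy`, deterministic for a fixed graph), and
their agreement with the secondary groupings is reported as an adjusted
Rand index. Clusters whose strongest projected edge points outside their
own grouping are flagged equivocal — these are exactly the clusters whose
membership deserves individual scrutiny. This statistic is a package
addition, not a reimplementation of any published visual procedure.

# Delineation criteria and outlier handling

Three criteria govern the translation of groupings into a scheme: units
must not nest (cells belong to one bioprovince, bioprovinces to one
bioregion — checked, not assumed), units should be geographically
coherent (measured as the fraction of cells in the largest connected
component under queen adjacency, with longitude wrapping across the
antimeridian), and the cluster structure should be supported by the
network consensus.

Clusters scattered across disjoint patches usually owe their unity to one
or two widespread, bathymetrically tolerant, or genuinely disjunct
(antitropical/bipolar) species, and treating them as cohesive provinces
would be a cluster-analysis artifact. `reassign_outliers()` therefore
iteratively moves each minority-component cell to the geographically
nearest cluster — candidates are clusters with a queen-adjacent cell,
falling back to centroid proximity — preferring maximal Jaccard
similarity between the cell's species set and the candidate pool, with
ties broken by smaller great-circle centroid distance. Every move is
logged with its rationale, and a manual override table takes precedence
and is never overridden back: expert judgement beyond the three criteria
(e.g. merging particular clusters into one province) is expressed through
that file, and the default heuristic is documented as an approximation of
it. Clusters below `min_cells = 2` cells with no adjacent neighbour
cluster are emitted as independent provinces — the remote-oceanic-island
case — rather than forced into a bioregion.

Unit indices are species richness S, genus richness G, the
diversification-rate proxy S/G, endemic count E (species found in no cell
outside the unit, with the whole dataset as denominator) and percentage
endemism 100·E/S. Ratios are rounded half-up to 2 decimals and
percentages to 1 decimal — half-up, not banker's rounding, because that
is the convention of the published tables these indices mirror, and the
package reproduces printed values exactly (e.g.
`province_indices(117, 50, 88)` gives ratio 2.34 and endemism 75.2%).

# The synthetic world

No global occurrence compilation with coordinates is bundled, so the
package ships a generator whose output has the statistical shape of one,
with ground truth attached. Provinces are rectangular blocks of grid
cells in distinct latitude bands, separated by at least one empty cell —
contiguity of the planted units is thus satisfiable by construction, which
is what makes the contiguity criterion a meaningful test. Default scale:
5 provinces × 10 cells × 80 species (≈ 400 species in 100 genera), mean
300 occurrences per cell (≈ 15,000 records), matching the compilation the
defaults emulate.

Pool composition per province with pool size S: `round(ef·S)` planted,
flagged endemics (`ef = endemic_fraction`, default 0.5); `round(o·S)`
species shared with each other province (`o` from the symmetric overlap
matrix, default 0.04 — under 5% pairwise sharing); and the remainder
filled with province-restricted species that are *not* flagged endemic.
The flagged fraction is what "recompute endemism from the truth" returns,
and it equals `ef` by construction up to rounding; the filler species
keep pool sizes exact without inflating cross-province sharing. This
last point is load-bearing: pool-level Jaccard dissimilarity between
provinces must stay above the 0.935 secondary cut for the planted
structure to be recoverable at all, which caps total sharing well below
`1 − ef`. The `endemic_fraction + Σ overlap ≤ 1` validity check enforces
the compositional budget.

Within a province, each species gets an occupancy probability drawn from
Beta(2, 2) per cell (mean 0.5, giving realistic patchiness and the
abundance skew that makes rarefaction curves informative) and a geometric
abundance propensity; cell occurrence totals are negative-binomial
(dispersion 5), allocated multinomially over the species present, with
every present species recorded at least once so planted occupancy is
exactly realized at full detection. Coordinates are uniform inside the
cell. `detection_prob` thins records to emulate under-sampling. The noise
stage then rewrites configured fractions of records — qualifier
insertion, `sp.` demotion, single-character misspellings (each paired
with an emitted synonym-table entry), out-of-range coordinates — in
exactly `round(rate · n)` copies each, with a perturbation log, so the
cleaning stage can be tested against a known answer.

One master seed feeds named substreams (taxonomy, occupancy, placement,
noise, layout), so a stage can be regenerated independently and a whole
run is byte-identical under the same seed, including layout coordinates.

What the generator does **not** emulate: coastline and bathymetry (blocks
are rectangles; real shelves are not), latitudinal diversity gradients,
spatial autocorrelation of sampling effort within provinces, phylogenetic
structure among species, and ecotones (province boundaries are hard).
Passing the planted-recovery tests therefore shows the pipeline is
correct and well-calibrated for compositionally distinct, spatially
coherent provinces; it does not show that any particular real fauna has
such structure, nor that the defaults are optimal for datasets whose
provinces blend gradually.

# Numerical and degenerate-input conventions

- Jaccard distances require ≥ 2 rows and no empty rows (filter first);
  identical rows give distance 0, disjoint rows 1.
- Merge-distance ties: smallest leaf-index pair, making dendrograms
  platform-independent.
- `rarefy` demands `1 ≤ n ≤ N`; `E[S_N] = S_obs` and `E[S_1] = 1` hold
  exactly, monotonicity and concavity are asserted property-style.
- Silhouette needs K ≥ 2; singleton clusters contribute 0.
- The adjusted Rand index of two identical trivial partitions (one block,
  or all singletons) is reported as 1, where the chance-correction
  denominator degenerates.
- A consensus report on a single cluster node carries an undefined ARI
  and an explanatory flag instead of a number.
- Empty record sets produce empty incidence matrices, not errors; an
  empty province is an error (indices would be 0/0).

# Problem sizes

The test suite runs the full pipeline on worlds of 3 provinces × 6 cells
(~900 records) for unit tests and the default 5 × 10 world (~15,000
records) for the recovery suites, with 20 replicate seeds for the
planted-recovery and consensus checks; the brute-force clustering oracle
covers 100 random instances per linkage at n ≤ 6, and the Monte-Carlo
rarefaction oracle uses 10,000 resamples on vectors with N ≤ 200. These
sizes were chosen so the planted structure is non-trivial (multiple
clusters per province, noise present) while a complete run stays in the
seconds range.

# Interface note

The package is library-first: `run_pipeline()` plus the stage functions
are the orchestration surface, and `scripts/acceptance.R` in the source
repository is a worked example of scripting a full run; no shell
subcommand wrapper is shipped.

# Known limitations

- The equal-angle grid gives unequal cell areas with latitude;
  an equal-area grid is out of scope, matching the visual conventions of
  the studies this workflow mirrors.
- Endemism is dataset-relative: a species endemic "to" a unit is merely
  unobserved elsewhere in the input, and under-sampling inflates E.
- The linkage actually used by any particular published analysis is often
  unrecorded; UPGMA is a defensible default, and the K chosen remains the
  analyst's responsibility.
- The outlier-reassignment heuristic approximates case-by-case expert
  reasoning; the audit log and the override table exist precisely because
  no heuristic should be trusted silently.
- Coverage-based richness extrapolation (Chao-type asymptotic estimators)
  is deliberately not included; the rarefaction module interpolates only.
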