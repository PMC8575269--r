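# bioregionize

Quantitative delineation of marine bioregions and bioprovinces from
georeferenced species occurrence records.

Global occurrence compilations (literature records, GBIF/OBIS downloads) are
noisy — open-nomenclature names (`aff.`, `cf.`, `indet.`), misspellings,
impossible coordinates — and unevenly sampled. This package implements a
complete, reproducible pipeline that turns such a table into a hierarchical
biogeographical scheme, the workflow used in global studies of benthic
faunas such as living brachiopods (~400 species, ~100 genera, ~15,000
occurrences worldwide):

1. **Cleaning** (`clean_records`): qualifier detection and rejection,
   `sp.`/`spp.` records retained for genus-level analysis only, synonym
   reconciliation, coordinate validation and normalization, optional land
   mask, duplicate collapsing.
2. **Gridding** (`build_incidence`, `filter_cells`): occurrences are mapped
   onto 5° latitude–longitude cells (half-open intervals, labels such as
   `"35°N130°E-30°N135°E"`); binary cell × taxon incidence matrices are
   built at species and genus level, and clustering is restricted to cells
   with ≥ 7 species.
3. **Rarefaction** (`rarefy`, `rarefaction_by_stratum`): individual-based
   (Hurlbert) expected richness
   `E[S_n] = Σ_i [1 − C(N−N_i, n)/C(N, n)]`, evaluated in log space, per
   climatic zone (30° bands per hemisphere) or 5° latitudinal bin, with a
   terminal-slope diagnostic of sampling completeness.
4. **Two-stage clustering** (`jaccard_distance`, `agglomerate`, `cut_k`,
   `secondary_grouping`): Jaccard dissimilarities
   `d(A,B) = 1 − |A∩B|/|A∪B|` between cell species sets, agglomerative
   (UPGMA by default) clustering with deterministic tie-breaking, elbow
   (within-cluster sum of squares) and silhouette diagnostics for K, then a
   secondary clustering of the K cluster pools cut at dissimilarity 0.935
   to yield the major groupings.
5. **Network verification** (`build_bipartite`, `layout_force`,
   `consensus_communities`): a bipartite cluster–species network, a
   ForceAtlas2-style force-directed layout (scaling 10, gravity 1, edge
   weight influence 1, tolerance 0.1), and a quantitative consensus check —
   greedy-modularity communities on the projected cluster graph compared to
   the cluster groupings by adjusted Rand index.
6. **Delineation** (`reassign_outliers`, `build_scheme`,
   `compute_indices`): groupings become bioregions and clusters become
   bioprovinces under three criteria (no nesting, spatial contiguity under
   queen adjacency, network support); scattered outlier cells — e.g. cells
   linked only by widespread or antitropical species — are reassigned to
   their most similar geographic neighbour; small remote clusters become
   independent provinces; each unit gets richness S, genus richness G, the
   diversification-rate proxy S/G (half-up, 2 decimals) and percentage
   endemism 100·E/S (half-up, 1 decimal).

A **synthetic world generator** (`generate_world`, `corrupt_records`) plants
rectangular provinces with configurable endemism, pairwise species sharing,
Beta(2,2) occupancy, negative-binomial sampling and record-level noise, and
emits ground truth — so every stage of the pipeline is testable without any
external data.

## Worked example

```r
library(bioregionize)

cfg <- run_config(
  world = world_config(noise = noise_config(qualifier_rate = 0.02,
                                            sp_rate = 0.02,
                                            misspelling_rate = 0.02,
                                            bad_coord_rate = 0.02)),
  seed = 42)
res <- run_pipeline(cfg)
print(res)
#> Bioregionization run
#>   records: 15644 raw -> 15018 kept (626 rejected)
#>   cells: 50 occupied, 50 clustered (richness >= 7)
#>   clustering: K = 20 -> 5 groupings (cut 0.935)
#>   scheme: 5 bioregions / 9 bioprovinces
#> <bioscheme: 5 bioregions, 9 bioprovinces>
#>   Bioregion A (provinces: 3): S = 76 (G = 49) [ratio 1.55], endemics 65 (85.5%)
#>   Bioregion B (provinces: 4): S = 78 (G = 54) [ratio 1.44], endemics 67 (85.9%)
#>   ...
#>   criteria: nesting TRUE, min contiguity 1.00, network ARI 1.00
```

The five planted provinces come back as five bioregions; 626 records are
rejected (the injected qualifier and bad-coordinate noise), every
bioprovince is spatially contiguous after outlier reassignment, and the
network communities agree with the cluster groupings exactly (ARI 1.0).

The per-unit index arithmetic is exposed directly, e.g. for a unit with 117
species in 50 genera of which 88 occur nowhere else:

```r
province_indices(117, 50, 88)
#> S = 117 (G = 50) [ratio 2.34], endemics 88 (75.2%)
```

## Documentation

The methods vignette (`vignettes/bioregionalization.Rmd`) describes the
model assumptions, the synthetic-world design, numerical conventions
(tie-breaking, rounding, boundary handling) and known limitations.
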