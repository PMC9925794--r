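# crocdiv

Three-dimensional biodiversity analysis on a geographic grid, built for
conservation assessments of species groups mapped by range polygons —
crocodilians being the motivating case. Given species ranges, a mixed-type
trait table, a phylogeny, a protected-area (PA) layer and an
ecosystem-service raster, the package computes per-cell diversity in three
dimensions, tests it against randomization nulls, measures how well each
species is represented inside the PA network, and maps threshold-based
conservation priorities. A deterministic synthetic-data generator produces
every input, so the whole pipeline runs and is tested without any external
spatial database.

## The statistics at the core

Working on a 0.5° longitude/latitude grid with half-open cells, the package
builds a binary presence/absence matrix by superimposing range polygons on
the grid, then computes per cell:

- **TD** (taxonomic diversity): species richness, the row sum of the
  presence matrix.
- **FD** (functional diversity, Petchey–Gaston): Gower distance on the
  species × trait matrix (range-normalized numeric differences, 0/1
  categorical mismatches, pairwise renormalization over missing values) →
  UPGMA dendrogram → sum of the branch lengths of the dendrogram subtree
  spanned by the cell's species.
- **PD** (Faith's phylogenetic diversity): the same branch-length sum on the
  phylogeny; by default the subtree is connected to the root, the common
  Faith convention.

Departures of FD and PD from chance are assessed with **independent-swap
null models**: 2×2 checkerboard submatrices are repeatedly flipped, which
preserves every site richness and species frequency exactly; one-tailed rank
p-values `(#{null ≥ obs} + 1)/(n_reps + 1)` flag each cell as `higher`,
`lower` or non-significant at α = 0.05. An unconstrained shuffle null is
also available.

PA effectiveness per species uses the **Mean Percentage Overlap**,
`MPO = 100 × mean over occupied cells of the cell fraction covered by the
PA union`, compared against a null that redraws the species' range size in
cells uniformly from its biogeographic realm. Flags and IUCN categories
combine into four representativeness patterns (i–iv), from
threatened-and-underprotected to non-threatened-and-well-covered.

Conservation priorities follow three nested threshold models: level k
selects cells whose FD, PD and TD all exceed `f_k · mean(X) / divisor`
(f = 0.9, 0.7, 0.5) and that contain a CR, EN or VU species respectively,
each level excluding cells already assigned. The published divisor table is
reproduced literally (`as_printed`); a quantile reading (`normalized`) is
available. Areas are spherical (authalic radius 6371.0088 km) throughout.

## Worked example

```r
library(crocdiv)

cfg <- synth_config(n_species = 12, extent = c(0, -10, 20, 10),
                    range_size_median_cells = 30, pa_patch_count = 20, seed = 7)
bundle <- simulate_bundle(cfg, tempfile("bundle"))
run <- run_pipeline(bundle$dir, tempfile("run"),
                    fd_pd_reps = 199, mpo_reps = 999, seed = 1)
#> rasterized 12 species onto 1600 cells
#> species absent from the phylogeny, excluded from PD: sp05

run$diversity_correlations[, c("pair", "pearson_r", "preferred")]
#>    pair pearson_r preferred
#> 1 TD-FD 0.9971652  spearman
#> 2 TD-PD 0.5577234  spearman
#> 3 FD-PD 0.5531844  spearman

summarize_representation(run$representation)
#> $pct_lower   [1] 50
#> $pct_higher  [1] 25
#> $pct_ns      [1] 25

head(run$representation[, c("species_id", "mpo_observed", "mpo_null_mean",
                            "flag", "iucn_category", "pattern")], 3)
#>      species_id mpo_observed mpo_null_mean          flag iucn_category pattern
#> sp01       sp01     0.000000      13.12377         lower            LC      ii
#> sp02       sp02    16.705400      13.35209 ns_above_mean            VU       i
#> sp03       sp03    16.957989      16.39844 ns_above_mean            LC      ii

table(run$priority$level)
#>    1    2    3 none
#>   49   27   51 1473
```

Reading the output: TD–FD correlate at r ≈ 0.997 across cells (FD is
richness-driven when traits carry no spatial structure); half the species
are significantly *under*-represented in the synthetic PA mosaic (e.g.
`sp01`, whose observed MPO of 0% falls below all 999 null draws of ≈13%);
and 49 cells qualify as very-high-priority (model 1: high TD/FD/PD plus a
Critically Endangered species present).

The package also ships the species-level representation summary for the 28
real crocodilian species:

```r
summarize_representation(crocodilian_representation())
#> $pct_lower   [1] 25
#> $pct_higher  [1] 57.1
#> $pct_ns      [1] 17.8
```

A thin CLI over the same functions lives at `inst/cli/crocdiv.R`
(subcommands `simulate`, `run`, `report`).

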