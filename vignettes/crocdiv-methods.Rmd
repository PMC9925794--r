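---
title: "Methods: gridded three-dimensional diversity, PA gap analysis and prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded three-dimensional diversity, PA gap analysis and prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crocdiv)
```

`crocdiv` implements a complete desk pipeline for conservation assessment of
a species group mapped by range polygons: per-cell taxonomic, functional and
phylogenetic diversity on a geographic grid, null-model significance,
protected-area (PA) gap analysis through the Mean Percentage Overlap (MPO),
threshold-based spatial prioritization, and realm-level correlation of
diversity with an ecosystem-service surface. This vignette explains the
procedures, their assumptions, the tunable parameters, and the design
decisions taken where a choice was genuinely open.

## The grid and geometry model

All geometry lives in longitude/latitude degrees (WGS84 convention); there
is no projected coordinate system anywhere in the core. The analysis grid is
a regular lattice (default 0.5°) with *half-open* cells
`[west, east) × [south, north)`, so any point — in particular a range
centroid sitting exactly on a cell boundary — belongs to exactly one cell.
Cell ids are 0-based and row-major from the south-west origin.

Areas are spherical, on the authalic sphere R = 6371.0088 km. A cell's area
is the exact zone formula `R²·Δλ·(sin φ_top − sin φ_bottom)`; the area of an
arbitrary polygon (or of a union of polygons, counted without double
coverage) is obtained by decomposing the longitude axis into slabs at every
vertex and inter-polygon edge crossing and integrating the union of latitude
intervals with 3-point Gauss–Legendre quadrature per slab. For sub-degree
slabs the quadrature error is ~1e-13 relative — far below the 1e-9
tolerances the tests assert. The package carries its own small polygon layer
(WKT text interchange, Sutherland–Hodgman clipping against cell rectangles,
even-odd interiors so holes need no special casing); ranges and PA layers
are therefore plain CSV files with a WKT column, and rasters are ESRI ASCII
grids — every artifact is inspectable text.

Rasterization offers three membership rules. The default,
`any_intersection`, marks a cell as occupied on any positive overlap: range
maps drawn from expert polygons already overestimate occupancy, and this
rule is the simplest faithful reading of superimposing polygons on a grid.
`centroid_within` and `min_fraction(f)` are available for sensitivity
analysis. Note that for a strongly concave or multi-part range the centroid
can fall *outside* the range, so the documented superset relation between
the two rules is guaranteed only for convex ranges.

## Diversity in three dimensions

**TD** is the presence-matrix row sum. **FD** follows the Petchey–Gaston
protocol: species × trait matrix → Gower distance → UPGMA dendrogram →
branch-length sum of the subtree spanned by the community.

The Gower distance handles the mixed trait schema declaratively: each trait
is declared `continuous`, `ordinal`, `categorical` or `binary` in a sidecar
YAML schema rather than hard-coded, because published trait lists for the
same group differ in how compound traits (e.g. skull shape) are counted.
Numeric traits contribute range-normalized absolute differences, with the
range taken over the *full* species pool — a per-cell range would make the
dendrogram, and therefore FD, cell-dependent. Categorical and binary traits
contribute 0/1 mismatches. Missing values are handled by pairwise
renormalization (the trait drops out of the pair's average); a trait with
zero range is excluded with a warning since its normalized difference is
undefined; a species pair sharing no observed trait is an error, never a
silent zero.

UPGMA is implemented with average-linkage updates and node heights at half
the merge distance, so the dendrogram is ultrametric and the cophenetic
distance between two species equals their merge distance. When two candidate
merges are exactly tied, the pair whose sorted labels are lexicographically
smallest merges first: floating-point tie order is the one place where
platform differences could change the dendrogram, and this rule pins it
down. On tie-free inputs the result is identical to
`hclust(method = "average")`, which the tests verify independently.

**PD** is Faith's index: the branch-length sum of the minimal phylogeny
subtree spanned by the cell's species. Both FD and PD use the same
`subtree_branch_sum()` with `include_root = TRUE` by default — the common
Faith convention, under which a single-species cell scores its root-to-leaf
path rather than zero. The flag is configurable because the literature uses
both conventions. A phylogeny may cover only part of the species pool (the
crocodilian reference tree covers 27 of 28 species); missing species are
excluded from PD per cell and reported once, while FD requires the
dendrogram to cover every species — it is built from the same trait table,
so a gap there is a data error. Internally, per-cell sums are computed
through an edge × species incidence matrix, which turns the
whole-grid computation into one matrix product per randomization replicate;
the tree-walk and matrix routes cross-validate in the tests, alongside a
brute-force subset oracle and `picante::pd`.

Cross-metric Pearson correlations are reported with two-sided p-values,
per-variable Shapiro–Wilk normality checks (on an evenly thinned subsample
of at most 5000 cells, the statistic's supported size) and Spearman's rho;
when either variable fails normality at 0.05 the Spearman statistic is
marked preferred, but both are always reported.

## Null models

FD/PD significance uses the **independent swap**: repeatedly sample a 2×2
submatrix and flip it when it is a checkerboard, preserving all row and
column sums exactly. Each replicate randomizes the *observed* matrix
independently with `max(1000, 10 × fill)` attempted swaps (fill = number of
presences) — the attempted-swap count is not standardized in the literature,
and ten times the fill gives empirically stable mixing on matrices of this
density while staying cheap. The chain runs in compiled code with its own
seeded xorshift generator, so a replicate is a pure function of the seed and
identical across platforms. Rank p-values `(k+1)/(n+1)` are one-tailed in
both directions because the question is explicitly directional (higher or
lower than chance); they can never be 0. A cell whose richness equals the
species count cannot change under margin-preserving swaps: its null is
degenerate, its SES undefined, and its flag non-significant by construction.

The procedure's description in terms of "any species could occupy any cell"
corresponds to a different, unconstrained null; both are implemented
(`algorithm = "unconstrained_shuffle"` permutes each species' occurrences
over cells, preserving species frequency but not site richness), with the
independent swap as the default since it is the named method.

The MPO null redraws a species' range — its number of occupied cells —
uniformly without replacement from its **realm** (its majority region), not
from the global grid: PA coverage differs systematically between realms, and
testing a species against cells it could never occupy would bias the null.
1000 randomizations at p < 0.05 is the reference setting.

## PA gap analysis and prioritization

`MPO = 100 × mean(per-cell PA coverage over occupied cells)`, with coverage
the spherical-area fraction of each cell under the *dissolved* PA union
(overlapping reserves count once). MPO deliberately works on cell-unit
coverage, not exact polygon-on-polygon overlap: the analysis unit is the
grid cell throughout. The null flag and the IUCN category then classify each
species into pattern i (threatened, not over-represented — the alarming
cases), ii (non-threatened, not over-represented), iii (threatened but
significantly over-represented) or iv (non-threatened and over-represented).
Flag percentages are reported truncated to one decimal, matching how the
reference 5/28 = 17.857% is conventionally printed as 17.8.

The three prioritization models are threshold equations. In `as_printed`
mode level k's cutoff for metric X is `f_k · mean(X) / divisor(k, X)` with
f = (0.9, 0.7, 0.5) and the published divisor table (0.5 everywhere at
level 1; 0.7 for FD and 0.5 otherwise at level 2; 1.0 at level 3). Taken
literally these divisors make the level-1 cutoff 1.8 × the mean — so a
perfectly uniform landscape selects *nothing* — and the lone 0.7 divisor is
preserved verbatim even though it may well be a typographical artifact. The
`normalized` mode instead reads the thresholds as f-quantiles of the nonzero
per-cell distribution, the natural reading of "higher than 90% of the
total observed". Level sets subtract already-assigned cells cumulatively by
default; the literal reading (each level subtracts only the previous one)
would re-admit level-1 cells into level 3, so it is available but off.
Per-region area summaries intersect priority cells with region polygons
spherically; a region's total is the part of the masked grid it covers, so
a fully prioritized region reports exactly 100%.

## What the synthetic generator does and does not emulate

The generator exists so every stage has a controlled, fully deterministic
test bed. Its reference configuration — the package's synthetic study — is:
28 species on a 0.5° grid over a 140° × 80° window (44,800 cells, the same
order as a masked global tropical grid), log-normal range sizes with median
300 cells and σ = 1, a latitudinal richness peak at 5° with 15° Gaussian
decay, a PA mosaic of ~150 rectangular patches covering 15% of the region
(the magnitude of global terrestrial PA coverage), a nutrient surface
coupled to richness at r = 0.5, and range-size status quantiles
(0.25, 0.32, 0.54) reproducing the real crocodilian 7 CR / 2 EN / 6 VU / 13
NT-LC composition. One global seed fans out into per-component child seeds,
so ranges, traits, tree, PA and nutrient can be regenerated independently.

Ranges are connected blobs grown cell-by-cell (growth weighted by the
latitudinal gradient) and then polygonized, so range size in cells is exact
by construction — appropriate because every downstream statistic is
cell-based. The nutrient surface is
`c·z(TD) + sqrt(1 − c²)·noise_sd·ε`; with the default `noise_sd = 1` its
expected correlation with richness is the coupling `c` itself, which the
tests recover at couplings 0, 0.59 and 1.

What the generator does *not* emulate matters for interpreting green tests.
Traits and the phylogeny are drawn independently of geography, so synthetic
FD and PD carry no spatial signal beyond richness: the swap null correctly
finds almost no non-random cells, whereas real communities — with
phylogenetically conserved traits and spatially structured lineages — show
strong departures. Passing tests therefore demonstrate calibration and
correctness of the machinery, not that real data would look random. Likewise
there is no niche structure, dispersal limitation, coastline masking or
climate layer, and PA patches are placed independently of diversity, unlike
real reserve networks.

## Numerical choices and problem sizes

Tolerances: geometric assertions at 1e-9 (the quadrature is ~1e-13);
branch-sum cross-checks at 1e-12; rank-p ties broken with a 1e-9 slack so
that a replicate exactly equal to the observation counts as at least as
extreme. Degenerate inputs are handled explicitly: empty cells score
(0, 0, 0); constant variables yield `NA` correlations rather than NaNs;
swap-inert matrices return unchanged with a warning.

The shipped tests and the acceptance script size their simulations for a
single CPU: null calibration runs 199 replicates on ~600 cells (the
reference replicate count for the full analysis is 1000), the end-to-end
checks use 10–12 species on 1600–2400 cells, and the acceptance run uses
the full 44,800-cell reference configuration with 199 swap replicates and
1000 MPO randomizations. These sizes are the package's own choices for a
reproducible desk study; all counts scale through ordinary arguments.

## Known limitations

- No equal-area projected grids; latitude weighting is handled through
  spherical cell areas instead.
- The geometry layer targets the rectilinear shapes this pipeline produces;
  arbitrary self-intersecting polygons are rejected rather than repaired
  beyond dropping degenerate rings.
- Abundance-weighted diversity, alternative FD families (FRic, FDis, Rao),
  spatial-autocorrelation-corrected correlation models and
  complementarity-based prioritization are out of scope.
- The MPO realm assignment uses the majority realm of a species' occupied
  cells; trans-realm species are tested against a single realm's null.
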