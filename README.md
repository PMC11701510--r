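# tockytraj

Temporal trajectory analysis of Fluorescent Timer flow cytometry data.

## The problem

Fluorescent Timer reporters (Fast-FT) translate into a blue-emitting protein
whose chromophore matures irreversibly into a red-emitting form
(maturation half-life 4.1 h) that then decays slowly (half-life 122 h). The
blue:red balance of a single cell therefore encodes the time elapsed since a
transcriptional event — in developing T cells, since the T-cell receptor
signal that triggered the reporter. The difficulty is integrating this
two-dimensional temporal readout with the many-dimensional surface-marker
profile of the same cells, and extracting ordered developmental trajectories
from the mixture of cell states in a tissue.

`tockytraj` implements the full analysis chain for people doing exactly
that: flow cytometrists and computational biologists with per-cell CSV
exports of Timer + marker panels, and anyone who wants a fully synthetic,
seeded test bed for trajectory methods of this kind.

## The method

1. **Timer transform.** After threshold subtraction and quantile
   normalisation of the Timer blue (B) and red (R) channels, each
   Timer-positive cell gets a *Timer Angle*
   θ = atan2(R′, B′) ∈ [0°, 90°] (a proxy for time since transcription
   onset) and a *Timer Intensity* r = √(B′² + R′²). Angles are categorised
   into the five Tocky loci: New (0°), NPt (0–30°), Persistent (30–60°),
   PAt (60–90°), Arrested (90°).
2. **Autofluorescence-aware clustering.** Markers are normalised as
   x′ = max(0, x − θ_m)/span_m so sub-threshold autofluorescence maps to
   exactly zero, then PCA + seeded k-means cluster the cells.
3. **Timer-constrained ordination.** With Z (n×2, standardised Angle and
   Intensity) and S (n×p, standardised markers), the projection
   S\* = Z(ZᵀZ)⁻¹ZᵀS is decomposed by SVD, S\* = UDVᵀ. Marker scores are V,
   cell wa scores S·V, lc scores S\*·V; no χ² weighting is used, so S\* is
   exactly the fitted value of column-wise least squares of S on Z.
4. **Cluster network.** Clusters become nodes at their wa-score centroids;
   edges keep every pairwise distance up to the *minimal connecting
   threshold* (the bottleneck of the minimum spanning tree).
5. **Time-respecting pathfinding.** A Dijkstra variant traverses an edge
   only toward strictly greater mean Timer Angle, yielding angle-monotone
   developmental paths.
6. **Locus statistics.** Per-sample locus percentages and marker MFIs along
   a path, compared between groups with two-sided Mann–Whitney U tests and
   Benjamini–Hochberg adjustment.

A synthetic-data subsystem generates all inputs: exact piecewise closed-form
Timer kinetics, Gaussian spike-in clustering benchmarks, and two-group
cohorts with a planted multi-cluster trajectory.

## Worked example

```r
library(tockytraj)
sim  <- simulate_cohort(seed = 42)                     # 6 control vs 8 KO samples
pipe <- run_pipeline(sim$cells, sim$panel, k = 8, seed = 42)
pipe
#> <tocky_pipeline>
#>   cells:    14000 (13959 Timer-positive)
#>   clusters: k = 8
#>   network:   8 nodes, 10 edges
#> <tocky_path> 4 -> 8 -> 2 -> 1 -> 7  (cost 7.674)
```

The path is the minimum-cost cluster sequence whose mean Timer Angle
strictly increases — here it walks the planted developmental chain from the
youngest to the oldest archetype. The locus comparison along that path:

```r
pipe$locus_stats$comparison[, c("locus", "log2fc", "p_adjusted")]
#>        locus log2fc p_adjusted
#> 1        New -0.579    0.00111
#> 2        NPt -0.367    0.00111
#> 3 Persistent -0.394    0.00266
#> 4        PAt -0.311    0.00266
#> 5   Arrested  0.898    0.00111
```

The knockout group is significantly enriched in the Arrested locus
(log2 fold change +0.9, BH-adjusted p ≈ 0.001) — the planted late-Timer
accumulation, recovered end to end. `autoplot(pipe$cca)`,
`autoplot(pipe$network, path = pipe$path)` and
`plot_locus_composition(pipe$locus_stats$composition)` draw the standard
biplot, network and locus line chart.

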