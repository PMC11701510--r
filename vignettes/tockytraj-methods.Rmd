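---
title: "Models and methods behind tockytraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tockytraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tockytraj)
```

This vignette is the package's own account of its models and the choices
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The Timer reporter model

A Fluorescent Timer protein is translated with an immature, blue-emitting
chromophore that matures irreversibly into a red-emitting form. We model
the per-cell molecule counts with two coupled first-order equations,

$$\frac{dB}{dt} = k(t) - mB, \qquad \frac{dR}{dt} = mB - \delta R,$$

where $k(t)$ is the transcription(+translation) rate in molecules/hour,
$m = \ln 2 / t_{1/2}^{mat}$ the maturation rate and
$\delta = \ln 2 / t_{1/2}^{red}$ the red decay rate. Defaults are the
Fast-FT constants $t_{1/2}^{mat} = 4.1$ h and $t_{1/2}^{red} = 122$ h.
`timer_kinetics_params()` holds these; an optional extra blue degradation
rate is folded into the $mB$ loss term and defaults to zero, i.e. blue
loss is maturation only.

The transcription program is a single piecewise-constant window
(onset, rate, stop). On each constant-rate interval the system has a
closed form (`timer_step()`), so trajectories are exact to machine
precision — the test suite verifies them against a generic numerical
integrator (`deSolve`) to a relative $10^{-6}$ over 0–300 h, and recovers
both half-lives to 1% by log-linear fits (`fit_half_life()`), which is
also what `scripts/acceptance.R` reports.

Two consequences anchor the temporal interpretation downstream:

* under persistent transcription, $B$ saturates at $k/m$ while $R$
  accumulates, so the red:blue balance grows monotonically with time
  since onset;
* after transcription stops, $B$ vanishes with half-life 4.1 h and $R$
  then decays with half-life 122 h, so "blue-only" means recent onset and
  "red-only" means transcription arrested long ago.

## Timer Angle, Intensity and the five loci

`timer_transform()` normalises each Timer channel by subtracting its
positivity threshold, flooring at zero, and dividing by the 95th
percentile of its above-threshold values pooled across the cohort
(`norm_quantile`, configurable). The original package's normalisation is
described only by citation in the source literature, so this percentile
scheme is our documented stand-in; dividing both channels by a common-rank
quantile puts them on one unit scale so that 45° corresponds to balanced
blue/red signal. Then, per Timer-positive cell,

$$\theta = \operatorname{atan2}(R', B') \cdot 180/\pi \in [0, 90],
\qquad r = \sqrt{B'^2 + R'^2}.$$

Conventions, fixed deliberately:

* **Positivity** is `blue > threshold OR red > threshold`, strictly:
  thresholds mark the top of the reporter-negative distribution.
* **Boundary cells.** Blue-only cells get exactly 0°, red-only exactly
  90°; a cell whose both clipped channels are zero is not Timer-positive.
* **Loci.** New = {0°}, NPt = (0°, 30°), Persistent = [30°, 60°],
  PAt = (60°, 90°), Arrested = {90°}. Inclusivity of 30° and 60° in
  Persistent is a package decision; the loci definitions name only the
  interval endpoints.

## Autofluorescence-aware clustering

Cytometers are tuned so that negative cells span a wide numeric range;
everything below a per-marker threshold is noise. `threshold_normalize()`
maps markers to $x' = \max(0, x - \theta_m)/\mathrm{span}_m$ with
$\mathrm{span}_m$ = (99th percentile − threshold), so autofluorescence is
*exactly* zero and cannot attract clusters. No log or arcsinh transform is
applied after subtraction — values are treated as linear units throughout,
and the linear scaling is deliberate and documented here because the
alternative is unstated in the method's source material.

PCA (centred, unscaled — the thresholded scale is already commensurate)
feeds k-means with the leading components reaching 90% cumulative variance
(`var_target`). `k` is user-specified; no automatic selection is claimed,
though within-cluster sums of squares are reported for scanning a grid.
k-means runs 25 seeded restarts with starting centres drawn from the
*distinct* rows of the score matrix: thresholded cytometry data contain
large blocks of identical (all-zero) rows, and sampling raw rows would
make restarts collapse or fail on duplicate centres. For the same reason
we keep R's default Hartigan–Wong iterations rather than Lloyd: with
heavy duplication Lloyd frequently empties a cluster mid-iteration and
aborts, while Hartigan–Wong from distinct centres is robust; determinism
is over `(seed, n_restarts)` either way.

Spike-in recovery (`evaluate_spike_recovery()`) calls a cluster enriched
when its target fraction strictly exceeds 20% (parameter), predicts every
member of an enriched cluster positive, and reports the confusion-matrix
metrics.

## Timer-constrained ordination

With $Z$ ($n \times 2$; standardised Angle, Intensity) and $S$
($n \times p$; markers centred and scaled to unit sample sd), the
constrained part of the marker matrix is the projection

$$S^* = Z (Z^\top Z)^{-1} Z^\top S,$$

decomposed by thin SVD $S^* = U D V^\top$ with at most two axes (two
explanatory variables). Marker scores are the columns of $V$; cell
weighted-average scores are $S V$; linear-combination scores are
$S^* V = U D$; explanatory arrows are the Pearson correlations of each
$Z$ column with each wa axis, hence bounded by 1. There is no $\chi^2$
weighting anywhere: fluorescence is not count data, and the projection
formulation makes $S^*$ identical to column-wise least-squares fitted
values — the property the test suite checks against an independent
`lm()` oracle.

Open choices, resolved as follows:

* **sd convention** is the sample standard deviation ($n-1$) everywhere.
* **Z standardisation**: the default centres *and* scales. The method's
  description names only division by the standard deviation yet calls the
  result "standardised"; without centring, the non-zero column means of
  $Z$ would let the grand mean of $S$ leak into the constrained space. A
  `mode = "literal"` scale-only variant is kept for fidelity.
* **Score duality**: the published wa-score formula is garbled at source
  (its display is missing, and "$Y (p\times2) = SV$" is dimensionally
  inconsistent); we adopt the standard constrained-ordination duality
  above, which is the unique reading consistent with the stated shapes.
* **Sign convention**: the largest-magnitude entry of each $V$ column is
  made positive, so outputs are reproducible across linear-algebra
  backends.
* **Collinear $Z$** raises an error suggesting a ridge ($\varepsilon I$
  added to $Z^\top Z$, default 0).

## The cluster network

Nodes are clusters placed at the arithmetic mean of their Timer-positive
members' wa scores (clusters with no Timer-positive member carry no
temporal information and are dropped with a warning). The edge set keeps
every pairwise Euclidean distance up to the *minimal connecting
threshold*: the smallest value at which the distance graph is connected,
which equals the largest edge of the minimum spanning tree. We implement
that value exactly rather than on an integer percentile grid (the grid is
available as `mode = "grid"`); the achieved percentile among all
$\binom{m}{2}$ distances is reported. Ties at the threshold are all
included; coincident centroids yield zero-weight edges, not errors.

## Time-respecting pathfinding

`dijkstra_tocky()` is Dijkstra's algorithm with one modification: an edge
is traversable from $u$ to $v$ only when the mean Timer Angle of $v$
strictly exceeds that of $u$. The constraint orients every usable edge by
angle, so the searched graph is acyclic and the usual nonnegative-weight
optimality argument carries over; the suite verifies cost and
reachability against exhaustive enumeration of angle-increasing simple
paths on hundreds of small random networks. Decisions:

* "exceeds" is strict; an `epsilon` slack (default 0) can admit
  numerically equal means, at the cost of possibly reintroducing cycles —
  it is applied as `angle(v) − angle(u) > −epsilon`;
* among equal-cost optima the lexicographically smallest node-id sequence
  is returned (the tie rule is unstated at source; this one is
  deterministic and order-stable);
* `shortest_path_tree()` gives the one-to-all variant, and
  `trim_overlapping_paths()` post-processes an ordered list of paths so
  that each later path restarts at its last node shared with any earlier
  one — the convention used when reporting several trajectories from a
  common origin.

## Locus statistics

`locus_composition()` reports, per sample, the percentage of trajectory
cells in each locus relative to a parent population; the default parent
is all Timer-positive cells of the sample, and a biology-specific parent
gate can be supplied as counts. `compare_groups()` runs two-sided
Mann–Whitney U tests — exact when the pooled sample count is ≤ 20 with no
ties, otherwise the normal approximation with tie and continuity
correction — and adjusts within one readout family at a time (the five
loci of one quantity, or all clusters for abundance): the narrowest
defensible family, configurable by construction since the family is just
the rows passed in. Fold changes put the experimental group in the
numerator. For cluster abundance, tests run on within-sample percentages
while the reported `log2fc_counts` uses mean cell numbers with a
pseudocount (default 0.5 cells) guarding empty clusters — counts for the
fold change, percentages for the test, matching how such panels are
usually read.

## The synthetic-data subsystem

The generators define the study conditions for every test; they emulate
the statistical structure the pipeline relies on, not the biology.

**Kinetics** (`simulate_timer_kinetics()`, `timer_state()`): exact
closed-form trajectories plus observation noise — multiplicative
mean-one lognormal per channel and additive Gaussian autofluorescence.

**Spike-in benchmark** (`simulate_spikein_benchmark()`): 10,000 cells,
five markers, thresholds at 1000 raw units. Background components are
autofluorescence modes whose spread is clipped just below threshold —
with mode-specific means and a shared per-cell brightness factor, giving
the correlated, multi-modal sub-threshold structure that an unthresholded
clustering wastes clusters on — plus sliding-pair bright positive
populations; 2% of cells are spiked in at mean 3000 (sd 400) on the last
two markers, optionally bimodal. The sub-threshold clipping realises the
design in which background components sit at configurable fractions
below/above the thresholds; it is what makes recovery after thresholding
clean by construction, so the thresholding-benefit check is directional
(thresholded metrics at least match the unthresholded run) rather than a
numeric reproduction of any published figure, whose exact simulation
parameters are not available.

**Cohort** (`simulate_cohort()`): 6 control and 8 knockout samples of
1000 cells. Five archetypes encode a developmental chain as a sliding
bright-marker pair over six markers — consecutive archetypes share one
bright marker, so consecutive marker-space distances are constant and
every skip is strictly farther, which is what "planting a trajectory"
must mean geometrically for a distance-threshold network to recover it.
Archetype onset-age windows (2–12, 12–36, 36–90, 90–180, 160–300 h,
uniform) increase along the chain; the two late archetypes have switched
transcription off (2–8 and 24–60 h before observation), populating the
PAt and Arrested loci. Knockout samples multiply the last archetype's
abundance by 3 — the planted late-Timer accumulation. Noise defaults
(lognormal sd 0.25 on all channels, additive autofluorescence, marker sd
300) were chosen so that thresholding and locus assignment are
non-trivial but the planted effects dominate sampling noise at the
default sample sizes.

What the generators do **not** emulate: spectral spillover and
compensation artefacts, instrument drift between samples, doublets and
debris, heavy-tailed marker distributions, or any correlation between
marker noise and Timer state. Passing tests therefore demonstrate the
correctness and sensitivity of the algorithms under clean mixture
assumptions, not robustness to every artefact of real cytometry.

## Problem sizes and numerical tolerances

The suite runs the ordination oracle on hundreds of random instances with
$n \le 50$, $p \le 8$ at $10^{-9}$ max-abs tolerance; pathfinding on 500
random networks of up to 8 nodes against exhaustive enumeration; network
thresholds on 200 random centroid sets of up to 10 nodes; the spike-in
benchmark at $k \in \{8, 16, 24, 32\}$; and the cohort round trip over 20
seeded replicates at full design size (plus 100 lighter replicates for
the locus-statistics sign check). Kinetic fits are asserted to 1%, exact
statistics to $10^{-12}$. These sizes make the whole suite run in about a
minute while keeping each oracle exhaustive in its regime.

## Known limitations

* The Timer normalisation percentile (95th) is a stand-in for an
  upstream convention that is not published in full; results depend on it
  only through a per-channel rescaling, which leaves loci boundaries and
  angle ordering intact but shifts individual angles.
* Angle is undefined for Timer-negative cells; analyses that need every
  cell must gate or impute upstream.
* The network is built in the two constrained dimensions only; structure
  orthogonal to Timer progression is invisible to the pathfinder by
  design.
* With `epsilon > 0` the pathfinder's graph may contain short cycles
  among near-equal-angle nodes; costs remain correct (Dijkstra needs only
  nonnegative weights) but "time-respecting" then holds only up to the
  slack.
* k-means determinism is guaranteed for fixed `(seed, n_restarts)` on a
  fixed platform; bit-identical labels across BLAS builds are not
  promised.
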