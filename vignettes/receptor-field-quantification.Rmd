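---
title: "Quantifying postsynaptic receptor fields from dSTORM localizations"
author: "smlmFields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying postsynaptic receptor fields from dSTORM localizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmFields)
```

## The measurement problem

Direct stochastic optical reconstruction microscopy (dSTORM) of a tagged
glutamate-receptor subunit at the *Drosophila* neuromuscular junction yields a
point cloud: tens of thousands of single-fluorophore localizations, each with
a position (nm), an acquisition frame, and a fitted amplitude in camera A/D
counts. The biological quantity of interest is the *receptor field* — the
cluster of receptors opposite one presynaptic release site — summarised by
two numbers per field: how many localizations it contains and how much area
it covers.

`smlmFields` implements the full chain from localization table to field
statistics:

1. **Quality filter.** Only localizations with amplitude strictly over
   12,000 A/D counts enter the analysis (`filterByAdcount()`).
2. **ROI clipping.** Analysis is restricted to polygonal regions drawn on
   reconstructed, binned images at 10 nm px⁻¹ (`clipToRoi()`,
   `renderBinned()`); boundary points are retained.
3. **Cluster extraction.** Hierarchical density-based spatial clustering of
   applications with noise (HDBSCAN) partitions the points of each ROI into
   clusters plus noise (`extractClusters()`), with a two-parameter sweep and
   a stability rule to fix the parameters (`runSweep()`,
   `selectStableParams()`).
4. **Area measurement.** Each cluster's footprint is the area of its 2D
   alpha shape (`alphaShapeArea()`), with alpha chosen by a
   small-increase stopping rule on the population median
   (`areaVsAlphaSweep()`, `selectAlpha()`).
5. **Exclusion and summary.** Fields with area ≤ 0.03 µm² or ≥ 0.3 µm² are
   excluded (`applyExclusion()`); the survivors are summarised by
   interpolated percentiles and normalized histograms
   (`summarizeFields()`).

A companion module computes the derived measures of two-electrode
voltage-clamp recordings (quantal content, voltage-scaled mEPSC amplitudes,
paired-pulse ratios), and a synthetic-scene generator provides ground truth
for every stage.

## Density-based cluster extraction

HDBSCAN is governed by two parameters: the **minimum cluster size** (a
cluster must contain at least this many localizations) and **minimum
samples** (the k of the k-nearest-neighbour *core distance*, which smooths
the density estimate). The implementation follows the reference formulation:
core distances (distance to the minimum-samples-th nearest other point),
the minimum spanning tree of the mutual-reachability graph
`d_mr(a, b) = max(core(a), core(b), d(a, b))` (computed in C++), the
single-linkage hierarchy over that tree, the condensed tree at the minimum
cluster size, and excess-of-mass cluster selection. Two consequences worth
knowing:

* Data forming a single undifferentiated blob are returned entirely as
  noise — the root of the hierarchy is never a selectable cluster. Real
  ROIs always contain several fields, so this does not arise in practice.
* Points far from any cluster core (sparse background) may attach to a
  cluster at low density or stay noise depending on tie-level details;
  agreement with the reference Python implementation is exact on
  well-separated data and differs only for a handful of peripheral
  background points otherwise.

Cluster ids are deterministic: ordered by decreasing size, ties broken by
the smallest member index.

**Parameter sweep.** The sweep axes replicate the reference grid — minimum
cluster size 10–100 in steps of 10; minimum samples 2, 5–25 in steps of 5,
30–100 in steps of 10; 140 combinations — and record the median number of
clusters per image. "Set in the stable range" is operationalised as a
plateau rule: a cell qualifies when its median count differs by at most 10%
(relative) from every 4-neighbour; qualifying cells form 4-connected
plateaus; the largest plateau wins and the anchored default (40, 10) is
returned whenever it lies inside. This is a documented heuristic — the
reference choice was partly judgment — and both the tolerance and the
anchor are arguments of `selectStableParams()`.

The sweep is computed on *unfiltered* clusters; the area exclusion is
applied downstream only. The hierarchy of an image depends only on minimum
samples, so it is built once per minimum-samples value and re-condensed for
each minimum cluster size.

## Alpha-shape areas

The alpha shape of a cluster is the union of its Delaunay triangles with
squared circumradius at most alpha (nm²) — so `alpha = x²` retains
triangles whose circumcircle radius is at most x nm. The criterion is
inclusive at equality, making constructed examples exact. Each cluster is
triangulated alone; a pooled triangulation masked by labels would let
cross-cluster triangles contaminate areas. Clusters with fewer than three
distinct points, or collinear ones, get area 0 and a degeneracy flag; the
lower exclusion bound removes them downstream.

**Choosing alpha.** Area is nondecreasing in alpha, rising towards the
convex-hull area. On the grid `alpha = x² nm²`, x = 5, 10, …, 200, the
package computes the median area across all clusters (pooled, as in the
reference analysis pooling all clusters) and selects the first alpha whose
per-step increase of the median falls strictly below 5%. The first grid
alpha has no predecessor step and is never selectable. On the synthetic
study-condition preset the rule selects 8100–9025 nm² depending on seed,
matching the reference working value of 9025 nm².

## Exclusion and summaries

Fields with area ≤ 0.03 µm² or ≥ 0.3 µm² are excluded — both bounds
themselves excluded, following the reference protocol wording. Excluded rows are kept
in an audit table (attribute `"excluded"`, with reasons) so that
counts-before/after accounting is reproducible. Percentiles use linear
interpolation between order statistics (type 7, the common default;
oracle-tested); histograms are equal-width with heights normalized to a
total of 1.

## Electrophysiology-derived measures

Recordings enter the analysis only if the initial membrane potential is at
least as hyperpolarized as −50 mV and the membrane resistance at least
4 MΩ (both inclusive). Quantal content is the mean evoked EPSC amplitude
divided by the mean miniature EPSC amplitude of the same cell, with minis
recorded at −80 mV scaled to the evoked holding potential of −60 mV
assuming a linear current–voltage relation and a 0 mV reversal — a factor
of exactly 0.75. The paired-pulse ratio averages first- and second-pulse
amplitudes across traces before taking the ratio. Amplitudes are stored
signed (inward negative); all derived ratios are sign-invariant. The module
starts from event-amplitude tables: event detection from raw traces is a
separate (commercial-software) step outside its scope.

## The synthetic-scene generator

`simulateScene()` emulates the statistical structure the analysis assumes:
fluorophores placed uniformly inside each ground-truth shape (disk, ellipse
or polygon), a geometric number of blinks per fluorophore (minimal blinking
model; a fixed count is available for exact-count tests), isotropic Gaussian
localization error per blink, uniform random frames, amplitudes drawn above
the 12,000 A/D threshold (a configurable fraction below), and a homogeneous
Poisson background over the ROI. Identical seed and parameters give
bit-identical output, and the caller's RNG state is untouched.

The study-condition preset (`paperLikeScene()`) draws cluster areas from a
log-normal with median 0.15 µm² truncated to (0.03, 0.3) µm², uses 20
fluorophores × mean 4 blinks ≈ 80 localizations per cluster, σ = 10 nm
localization precision (typical for Alexa Fluor 647 dSTORM), background
1 µm⁻², and a 4 µm grid pitch so that neighbouring fields stay several
diameters apart. The per-cluster fluorophore count is a stand-in — the
study reports only the ~80 localizations per cluster, not how many
labelling sites produced them — and the 20 × 4 split is adopted because
under it the alpha-selection rule reproduces the reference alpha almost
exactly, suggesting a comparable blink microstructure.

What the generator does **not** model: per-frame on/off photokinetics,
photon-count statistics, detector noise, drift, or multiple localizations
merged across frames. Passing recovery tests therefore demonstrate
correctness of the analysis chain on data satisfying its assumptions, not
robustness to acquisition artefacts.

## Known limitations

* **Footprint underestimation.** The alpha shape of a *finite* localization
  sample lies inside the convex hull of that sample, which itself covers
  only ≈ 1 − c·n^(−2/3) of the generating region for n uniform sites (about
  89% at n = 80, less when blinks cluster at fewer sites). At the
  study-condition sampling density the measured median area is roughly half
  the generating disk area, and no admissible choice of the
  fluorophore/blink split brings the pipeline's estimate within 15% of the
  generator's true area. This is a property of footprint estimation from
  sparse samples, not of the implementation: the same effect applies to the
  absolute areas reported by this protocol, which should be read as alpha-shape footprints
  at the chosen alpha rather than as unbiased region areas. Localization
  *count* recovery is unbiased and accurate.
* Cluster-count recovery on well-separated study-condition scenes is ≥ 95%
  over seeds (typically 99/100), with rare over-splits of one field.
* The clustering operates on (x, y) only; frame-aware blink merging and 3D
  analysis are out of scope.

## Problem sizes used by the test-suite

The suite exercises scenes of 4–50 clusters (≈ 300–5,000 localizations),
100-seed repetitions for the stochastic guarantees, 100 random point sets of
up to 300 points for the geometry oracles, and 200 simulated cells for the
quantal-content estimator — sizes at which every oracle comparison is exact
and each test file runs in seconds to a few minutes.
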