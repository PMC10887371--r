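# smlmFields

Quantification of postsynaptic receptor fields from single-molecule
localization microscopy (dSTORM), plus the derived measures of two-electrode
voltage-clamp recordings, for synapse biologists working at the *Drosophila*
neuromuscular junction (or any preparation producing localization tables and
event-amplitude tables of the same shape).

A dSTORM experiment reduces a tagged glutamate-receptor subunit to a point
cloud of localizations (x, y in nm; frame; fitted amplitude in A/D counts).
`smlmFields` turns that cloud into per-field statistics:

* **Intensity filter** — only localizations with amplitude > 12,000 A/D
  counts are analysed.
* **ROI handling** — polygon regions drawn on reconstructed binned images
  (10 nm px⁻¹), with inclusive point-in-polygon clipping.
* **Cluster extraction** — HDBSCAN (hierarchical density-based spatial
  clustering of applications with noise), implemented from core distances,
  mutual-reachability minimum spanning tree (C++), condensed tree and
  excess-of-mass selection; plus the reference two-parameter sweep
  (minimum cluster size 10–100 step 10 × minimum samples
  {2, 5–25 step 5, 30–100 step 10} = 140 combinations) and a
  plateau-stability rule anchored at (40, 10).
* **Area measurement** — 2D alpha shapes: a Delaunay triangle is kept iff
  its squared circumradius R² ≤ α (nm²); the field area is the summed area
  of kept triangles. α is chosen on the grid α = x² nm², x = 5…200 step 5,
  as the first value whose step increase of the median cluster area falls
  below 5%.
* **Exclusion and summaries** — fields with area ≤ 0.03 or ≥ 0.3 µm² are
  excluded (audit table kept); box-plot statistics use interpolated
  percentiles (median, quartiles, 10th/90th whiskers) and histograms are
  normalized to unit total.
* **Electrophysiology** — cell inclusion (Vm ≤ −50 mV, Rm ≥ 4 MΩ), mEPSC
  scaling from −80 to −60 mV under a linear I–V with 0 mV reversal
  (× 0.75 exactly), quantal content = mean eEPSC / scaled mean mEPSC,
  paired-pulse ratio of averaged traces (30 ms interval).
* **Synthetic ground truth** — a seeded scene generator (clustered
  fluorophores with geometric blinking, Gaussian localization error,
  Poisson background) and a voltage-clamp cell simulator, so every stage is
  testable against known truth.

## Worked example

```r
library(smlmFields)

scene <- paperLikeScene(nClusters = 12, seed = 7)   # study-condition preset
sim   <- simulateScene(scene)
sim$locs
#> LocalizationTable with 1177 localizations
#>   x: [72.8, 15884.2] nm   y: [2.7, 11961.2] nm
#>   frames: 7-14997 of 15000   adcount median: 21029
#>   channel pixel size: 127 nm/px

locs <- filterByAdcount(sim$locs, 12000)            # strict "over 12,000"
cs   <- extractClusters(locs, clusterParams(40, 10))
cs
#> ClusterSet 'roi': 12 clusters over 1177 localizations (109 noise)
#>   params: minClusterSize=40, minSamples=10

pts   <- clusterPoints(locs, cs)
alpha <- selectAlpha(areaVsAlphaSweep(pts))          # first <5% step
alpha
#> [1] 8100

fields <- receptorFields(locs, cs, alpha = alpha)
kept   <- applyExclusion(fields)                     # 0.03 < area < 0.3 um^2
#> 0 of 12 receptor fields excluded by area criteria
summarizeFields(kept)
#> FieldSummary of 12 receptor fields
#>   area um^2: median 0.0713 [q25 0.0643, q75 0.0765] (p10 0.0631, p90 0.0979)
#>   locs:      median 87.5 [q25 82.5, q75 97.5] (p10 73.8, p90 105.6)
```

All twelve simulated fields are recovered, each with ≈ 80–90 localizations
(the generator's 20 fluorophores × mean 4 blinks). The selected alpha
(8100 nm², i.e. x = 90 nm) sits at the reference working point; the median
alpha-shape footprint is smaller than the generating disk areas — see the
vignette for why footprints of ~80-localization samples systematically
underestimate the generating region.

Electrophysiology works the same way from amplitude tables:

```r
cells <- simulateCells(10, trueQc = 50, cv = 0.1, seed = 7)
quantalContent(cells[[1]])
#> QuantalResult 'cell001': quantal content 49.33
#>   (eEPSC -37.88 nA / scaled mEPSC -0.768 nA), PPR 0.96
```

## Layout

| Path | Content |
| --- | --- |
| `R/` | S4 classes, I/O, HDBSCAN core, alpha-shape geometry, field statistics, electrophysiology, simulators |
| `src/` | mutual-reachability MST (Rcpp) |
| `tests/testthat/` | unit, property and acceptance tests with independent oracles |
| `vignettes/receptor-field-quantification.Rmd` | methods notes: models, parameters, numerical conventions, limitations |
| `scripts/acceptance.R` | end-to-end reproduction script |
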