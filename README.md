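# corneaMADM

Quantification of MADM-labeled corneal endothelial mosaics in R.

Mosaic analysis with double markers (MADM) labels the two daughters of a
single mitotic recombination event with heritable colors: a G2-X event
yields a red and a green sibling, and in the GR-MADM configuration the
green daughter is homozygous mutant while its red sibling is homozygous
wild-type. Inside one corneal endothelium this provides a matched,
cell-autonomous comparison of mutant and wild-type clones. The package
implements the complete image-quantification pipeline for such
experiments, together with a generative simulator so every stage can be
validated against exact ground truth:

* **Simulator** (`simulationConfig`, `madmPreset`, `generatePositions`,
  `simulateMadm`, `renderChannels`, `renderJunctions`) — blue-noise
  monolayer geometry, G2-X/G2-Z/G0-G1 event logic, genotype-specific
  clonal expansion (clone size `1 + Poisson(1.6·fold − 1)`, mean exactly
  `1.6·fold`) and dispersal (per-division Gaussian walk with hard-core
  exclusion), and rendering to two-channel panoramas (248/82 ≈ 3.024
  µm/px) and junction-label images, with Poisson noise and bleed-through
  streak artifacts.
* **Junction segmentation** (`detectCells`, `morphometrics`,
  `cellDensity`, `sampleRegions`) — smoothing, ridge enhancement,
  h-minima seeding and a Dirichlet/Voronoi partition of seed centroids;
  per-cell area, circularity `4πA/P²`, neighbor counts, and regional
  (4 central + 4 peripheral fields) density estimates with half-weighted
  border cells.
* **Labeled-cell detection** (`detectLabeledCells`, `classifyColor`) —
  band-pass filtering, elongation-based streak rejection, local-maximum
  spot detection, cross-channel pairing and red/green/yellow
  classification with per-channel Otsu thresholds.
* **Twin spots** (`findTwinSpots`, `twinSpotStats`) — single-linkage
  grouping of single-labeled cells at the 248 µm (82 px) radius with the
  200 µm isolation rule and a deterministic overlap flag; size
  histograms and per-spot / pooled green-red ratios.
* **Dispersion clustering** (`sidcCluster`, `percentInClusters`,
  `clusterByColor`) — deterministic DBSCAN on centroids in physical µm
  at ε = 136 µm (45 px), minimum density 4; per-color
  percent-in-clusters.
* **Reporting** (`greenRedRatio`, `foldChange`, `summarizeCornea`,
  `batchSummary`, `runPipeline`) — per-cornea reports, tidy batch tables
  with means ± SEM, and an end-to-end driver
  (simulate → render → detect → twin spots → cluster → report).

See the methods vignette (`vignettes/madm-quantification.Rmd`) for the
model, parameter meanings and numerical choices.

## Worked example

Simulate one null-mutant ("KO-like") mosaic cornea and quantify it
end-to-end:

```r
library(corneaMADM)

cfg <- madmPreset("KO", seed = 7)   # green fold 6, low dispersal
res <- runPipeline(cfg, id = "ko_eye1")
res$report
#> CorneaReport ko_eye1 [GR-MADM]
#>   counts: red 10, green 54, yellow 33; green/red ratio: 5.4
nrow(spots(res$twinSpots))
#> [1] 7
round(res$clusters$percentInClusters, 1)
#>   red green
#>     0   100
```

This cornea carried 10 wild-type (red) and 54 mutant (green)
single-labeled cells — a green/red ratio of 5.4, the per-cornea estimate
of the ~6-fold clonal expansion planted by the preset — plus 33
double-labeled (yellow) heterozygous cells. Seven twin spots were found,
and every green cell sat in a dense cluster (percent-in-clusters 100%),
the signature of the low-dispersal phenotype; red wild-type cells formed
no clusters.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/madm-pipeline.R --preset KO --seed 7 --outdir out/
```

writing the detection, twin-spot and cluster CSV tables, channel TIFFs
and the report JSON.

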