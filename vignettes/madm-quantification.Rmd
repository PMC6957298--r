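---
title: "Quantifying MADM-labeled corneal endothelial mosaics"
author: "corneaMADM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying MADM-labeled corneal endothelial mosaics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneaMADM)
```

## The biological problem

Mosaic analysis with double markers (MADM) marks the two daughters of a
single mitotic recombination event with distinct, heritable colors. In a
monolayer such as the corneal endothelium, a G2-X segregation event yields
one red and one green sibling; in the GR-MADM configuration the green
daughter is homozygous mutant and the red daughter homozygous wild-type,
so the descendants of one cell division carry a built-in, same-tissue
control. Two readouts quantify the mutant phenotype:

* **Clonal expansion** — the green/red cell ratio, pooled over a cornea
  or computed per twin spot (the spatially coherent red+green group
  descending from one event). A mutant that divides more leaves more green
  cells per red sibling cell.
* **Dispersion** — how tightly the labeled descendants aggregate. A
  density-based clustering of cell centroids (a deterministic DBSCAN)
  summarizes each color as the percentage of cells assigned to any
  cluster.

Because no imaging data accompany these experiments in public form, the
package pairs every analysis stage with a generative simulator of labeled
monolayers, so that each stage is tested against exact ground truth.

## The generative model

`simulationConfig()` / `madmPreset()` define the model; `generatePositions()`,
`simulateMadm()`, `renderChannels()` and `renderJunctions()` realize it.

**Geometry.** The cornea is a disc of radius 1500 µm (from the reported
sampled fraction: ~0.25 mm² being 3.6% of the tissue gives a total area of
~6.9 mm², i.e. a radius of ~1.48 mm). Cell centers are drawn by Bridson
Poisson-disc sampling, randomly thinned to exactly
`round(density × area)` points, then regularized by one discrete Lloyd
relaxation step. This yields the blue-noise, near-hexagonal packing of a
confluent monolayer: the realized density equals the target exactly, the
Poisson-disc radius is ~74% of the mean spacing, and after relaxation the
minimum pairwise spacing remains above half the mean spacing. The default
density of 2500 cells/mm² matches a healthy adult endothelium.

**Events.** Each of `nEvents` recombination events draws a segregation
mode from `segProbs` (defaults: G2-X 0.25, G2-Z 0.25, G0/G1 0.5, so that
most labeled cells are yellow, as observed in flat-mounts). Event anchors
are placed with a minimum mutual spacing (400 µm for the rare WT-MADM
events, 300 µm for the denser mutant mosaics) because recombination
events are rare and widely distributed; the spacing caps are chosen below
the random-sequential-adsorption jamming limit of the disc so placement
always succeeds.

**Clonal expansion.** Each single-labeled founder expands into a clone of
size `1 + Poisson(cloneBaseMean × fold − 1)`. This law has mean exactly
`cloneBaseMean × fold` with minimum 1, so the expected pooled green/red
ratio equals the green fold when the red fold is 1 — the property the
green/red metric is designed to estimate. A truncation law such as
`max(1, Poisson(fold))` would not do this: its mean is `fold + P(0)`,
which inflates a fold-1 clone to 1.37 and deflates the recovered ratios
to 2.2 and 4.4 for folds 3 and 6. `cloneBaseMean = 1.6` makes the
wild-type twin-spot size distribution (2 + Poisson(1.2) cells) place
~88% of spots in the 2–4-cell range, matching the reported predominance
of small spots.

**Dispersal.** Clone members are laid out as a random walk from the
founder with per-division isotropic Gaussian steps of scale
`dispersalSigma[genotype]` (reflected at the disc boundary), with a
hard-core exclusion of 0.8× the mean cell spacing between labeled cells —
cells occupy space, and without the exclusion simulated clone members
could sit closer than any two real cells (and closer than the imaging
point-spread function) ever allow. At `dispersalSigma = 0` the exclusion
is disabled and members stack on the founder, the degenerate limit used
by the invariant tests.

**Presets.** `madmPreset()` encodes the three study conditions:

| preset | mode | green fold | dispersal (µm/division) | events |
|--------|------|-----------:|------------------------:|-------:|
| WT     | WT-MADM | 1 | 25  | 20 |
| CK     | GR-MADM | 3 | 300 | 40 |
| KO     | GR-MADM | 6 | 14  | 40 |

The CK-like mutant scatters widely (steps larger than the 136-µm
clustering radius, so its clones rarely form clusters); the KO-like
mutant stays packed at about one cell diameter per division, so its large
clones cluster almost completely. The per-division step sizes are not
reported quantities; they were fixed once to reproduce the qualitative
contrast (scattered vs. tightly packed progeny).

**Rendering.** Labeled cells become Gaussian spots (σ = 6 µm) in a
two-channel image at 248/82 ≈ 3.024 µm/px — the scale fixed by the
published equivalence of 82 px and 248 µm. Yellow cells render into both
channels at the same position. Optional background offset, Poisson photon
noise and green radial streaks (epithelial bleed-through in an undulating
flat-mount) complete the noise model. Junction-label images draw finite-width
bright ridges along the Dirichlet tessellation of the cell centers at
1 µm/px, reflecting the higher magnification used for boundary imaging.
Every stage draws from its own RNG stream derived from the configuration
seed in a fixed order (positions, events, channels, junctions), so a
configuration reproduces bit-identical monolayers and images.

## Junction segmentation and morphometry

`detectCells()` follows the classical filter-then-tessellate recipe:
Gaussian smoothing (σ = 1.5 µm), white-ridge enhancement by large-scale
background subtraction (8× the smoothing scale), seed extraction as
h-minima basins (watershed of the inverted image with flooding tolerance
10% of the dynamic range), and a Dirichlet/Voronoi partition of the seed
centroids (via deldir) clipped to the image window. Exact polygon
geometry — area, perimeter, shared-edge neighbor lists — comes from the
tessellation, avoiding pixel-staircase bias in perimeters.

Cells whose tile touches the window border are flagged `is_border`:
they are excluded from shape and area statistics and weighted ½ in
`cellDensity()` (the standard edge correction for counts in a bounded
frame). `morphometrics()` reports area, circularity 4πA/P² (clipped to
[0, 1]) and neighbor counts; `sampleRegions()` and `classifyRegion()`
implement the regional design of four central (within 1250 µm of the
apex) and four peripheral (within 200 µm of the cornea-sclera junction)
fields, one of each per quadrant, averaged separately by
`averageRegions()`.

On noise-free rendered fields of ≥400 cells the cell count is recovered
within 2% and the matched per-cell area with a median error below 5%;
density on a cropped region of interest is recovered within 5% of the
planted value. These recovery margins are what passing tests demonstrate;
real ZO-1 images add staining heterogeneity and out-of-focus structure
that the renderer does not emulate, so parameters (`segmentationParams()`)
remain configurable.

## Labeled-cell detection and classification

`detectLabeledCells()` band-pass filters each channel (difference of
Gaussians at 4 and 20 µm), thresholds by Otsu, rejects connected
components more elongated than 5:1 (the epithelial bleed-through streaks
are long radial structures, unlike round cell spots), finds local maxima
with duplicate suppression at 8 µm, and pairs red/green maxima within
5 µm into double-labeled detections. Classification thresholds are Otsu
splits of the detected-spot intensity distributions per channel, floored
at 25% of the brightest spot so that a single-color image cannot
misclassify its own noise floor; because every threshold is relative,
classification is invariant under joint rescaling of both channels. On
simulations at the default noise level, recall and precision against the
generator's truth table exceed 98%.

## Twin spots

`findTwinSpots()` formalizes "closely associated red and green cells
within a circle of defined radius" as single-linkage connected components
at the 248-µm grouping radius, restricted to single-labeled cells
(yellow cells are heterozygous and never twin-spot members). The two
formulations coincide for isolated groups. A component qualifies when it
contains both colors and satisfies the isolation rule (no non-member
single-labeled cell within 200 µm of any member; automatic whenever the
isolation distance does not exceed the grouping radius). Manual curation
of overlapping clones is replaced by a deterministic flag: components
wider than twice the grouping radius are retained but marked, and
`twinSpotStats()` excludes them by default. Note that two genuinely
overlapping events closer than the grouping radius are indistinguishable
from one event without ground truth; the flag is a diameter heuristic,
not an oracle.

## Density-based dispersion

`sidcCluster()` implements DBSCAN on centroids in physical micrometers
(size- and shape-invariant: detected blob geometry never enters), at the
published operating point ε = 136 µm and minimum density 4. "Minimum
density 4" is read as the neighborhood occupancy including the query
point, which makes 4 also the minimum attainable cluster seed size; the
exclusive convention is available via `clusteringParams(inclusive =
FALSE)`. Two departures from textbook DBSCAN make the output a function
of the point set alone: border points join the cluster of their nearest
core (ties broken toward the lowest point index) instead of the
first-discovered cluster, and cluster labels are ordered by each
cluster's lowest member index. A consequence of nearest-core border
assignment is that a cluster can end up with fewer members than the
minimum density when its border points are closer to another cluster's
cores; the definitional invariants (clusters anchored on core points,
noise not ε-reachable from any core) always hold. The implementation is
checked for exact membership agreement against an independent
by-definition oracle on hundreds of random instances.

`percentInClusters()` is the dispersion readout: the percentage of a
color's cells assigned to any cluster, computed per color
(`clusterByColor()`), since the two colors represent different genotypes.

Under the presets, KO-like mosaics exceed CK-like mosaics in green
percent-in-clusters in ≥95% of replicates. The wild-type preset,
however, sits near zero: with ~5 G2-X events per cornea and mean green
clone size 1.6, a wild-type cornea rarely contains 4 green cells within
one ε-neighborhood, so WT percent-in-clusters is 0 in most replicates.
A strict per-replicate ordering KO > WT > CK is therefore not a property
of these study conditions, and the suite instead asserts the mechanism
directly: at matched event number and expansion fold,
percent-in-clusters decreases in the dispersal scale in ≥95% of
replicates.

## Reporting

`greenRedRatio()` flags the ratio undefined when a cornea has no red
cells (counts are still reported); `foldChange()` reports mutant/control
folds and percent change; `summarizeCornea()` assembles a validated
per-cornea report (counts conserve the total number of detections) and
`batchSummary()` emits a tidy long-format table with per-genotype means ±
SEM — the table an off-the-shelf ANOVA would consume; no inferential
statistics are computed here. Both eyes of a simulated animal are treated
as independent replicates, since event number and timing are random and
uncorrelated between eyes.

## Numerical choices and problem sizes

* All lengths are micrometers internally; pixel conversions happen only
  at image I/O with the 248/82 µm/px default.
* Pixel indices are 0-based in the coordinate convention (x right,
  y down); image bounds are half-open; a cell at (100, 100) µm at
  3 µm/px peaks at 0-based pixel (33, 33).
* Ties in border-point assignment and cluster labeling are broken by
  lowest point index; detection duplicate suppression keeps the brighter
  spot.
* Degenerate inputs: constant junction images yield an empty tessellation
  with a warning; empty point sets yield empty assignments; zero red
  cells yield a flagged, NA ratio; zero-area polygons are dropped with a
  message.
* The validation suite runs simulations at full cornea scale
  (1500 µm radius, ~17,700 cells) for point-level analyses, and renders
  imaging fields of 400–1000 px for pipeline-level recovery; ratio
  recovery pools ≥200 events per preset, chosen so that three standard
  errors of the pooled ratio resolve the fold contrasts 1/3/6.

## Limitations

* The simulator is 2-D and single-plane; z-stack projection, stitching
  artifacts and nuclear counterstains are not modeled.
* Whether mutant clones grow by extra division rounds or faster cycling
  is not modeled; only final clone-size distributions are.
* The dispersal model is a per-division random walk with hard-core
  exclusion; directed migration and contact-mediated rearrangement are
  not represented.
* The streak-artifact model and its elongation filter are stand-ins for
  the manual curation a human operator applies to real bleed-through;
  detections retain no provenance of which filter removed them.
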