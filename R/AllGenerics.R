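#' Extract the cell table
#'
#' @param x a [SimulatedMonolayer-class] or [CellTessellation-class].
#' @param ... unused.
#' @return data.frame of per-cell records.
#' @export
setGeneric("cells", function(x, ...) standardGeneric("cells"))

#' Extract the detection table
#'
#' @param x a [LabeledCellSet-class].
#' @param ... unused.
#' @return data.frame of detections.
#' @export
setGeneric("detections", function(x, ...) standardGeneric("detections"))

#' Extract the twin-spot table
#'
#' @param x a [TwinSpotSet-class].
#' @param ... unused.
#' @return data.frame of twin spots.
#' @export
setGeneric("spots", function(x, ...) standardGeneric("spots"))

#' Extract per-point cluster labels
#'
#' @param x a [ClusterAssignment-class].
#' @param ... unused.
#' @return integer vector, 0 = noise.
#' @export
setGeneric("clusterLabels", function(x, ...) standardGeneric("clusterLabels"))

#' Pixel scale accessor
#'
#' @param x an object carrying a physical pixel scale.
#' @return micrometers per pixel.
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))

#' Endothelial cell density
#'
#' Density in cells per mm^2. Border cells (cells clipped by the field
#' of view) are counted with weight 1/2, interior cells with weight 1.
#'
#' @param x a [CellTessellation-class], or a numeric count of interior cells.
#' @param ... method-specific arguments; see [cellDensity,numeric-method].
#' @return density in cells/mm^2.
#' @export
setGeneric("cellDensity", function(x, ...) standardGeneric("cellDensity"))

#' @export
#' @describeIn cells cells of a simulated monolayer
setMethod("cells", "SimulatedMonolayer", function(x, ...) x@cells)

#' @export
#' @describeIn cells cell records of a tessellation
setMethod("cells", "CellTessellation", function(x, ...) x@cells)

#' @export
#' @describeIn detections detections of a labeled-cell set
setMethod("detections", "LabeledCellSet", function(x, ...) x@detections)

#' @export
#' @describeIn spots twin spots found by [findTwinSpots()]
setMethod("spots", "TwinSpotSet", function(x, ...) x@spots)

#' @export
#' @describeIn clusterLabels labels of a cluster assignment
setMethod("clusterLabels", "ClusterAssignment", function(x, ...) {
  x@points$cluster
})

#' @export
#' @describeIn pixelScale of a tessellation
setMethod("pixelScale", "CellTessellation", function(x) x@pixelScale)

#' @export
#' @describeIn pixelScale of a labeled-cell set
setMethod("pixelScale", "LabeledCellSet", function(x) x@pixelScale)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  cornea radius: %g um; target density: %g cells/mm^2\n",
              object@corneaRadius, object@targetDensity))
  cat(sprintf("  events: %d (g2x %.2f, g2z %.2f, g0g1 %.2f), min spacing %g um\n",
              as.integer(object@nEvents), object@segProbs[["g2x"]],
              object@segProbs[["g2z"]], object@segProbs[["g0g1"]],
              object@eventMinSpacing))
  cat(sprintf("  mode %s-MADM; fold WT %.2g / MUT %.2g; dispersal WT %g / MUT %g um\n",
              object@mode, object@expansionFold[["WT"]],
              object@expansionFold[["MUT"]], object@dispersalSigma[["WT"]],
              object@dispersalSigma[["MUT"]]))
  cat(sprintf("  pixel scale %g um/px (junctions %g); seed %d\n",
              object@pixelScale, object@junctionPixelScale,
              as.integer(object@seed)))
})

setMethod("show", "SimulatedMonolayer", function(object) {
  tab <- table(object@cells$color)
  cat(sprintf("SimulatedMonolayer: %d cells (", nrow(object@cells)))
  cat(paste(sprintf("%s %d", names(tab), as.integer(tab)), collapse = ", "))
  cat(sprintf("), %d events, seed %d\n",
              length(unique(stats::na.omit(object@cells$event_id))),
              as.integer(object@config@seed)))
})

setMethod("show", "CellTessellation", function(object) {
  cat(sprintf("CellTessellation: %d cells (%d border), %g um/px\n",
              nrow(object@cells), sum(object@cells$is_border),
              object@pixelScale))
})

setMethod("show", "LabeledCellSet", function(object) {
  tab <- table(factor(object@detections$class,
                      levels = c("red", "green", "yellow")))
  cat(sprintf("LabeledCellSet: %d detections (red %d, green %d, yellow %d)\n",
              nrow(object@detections), tab[["red"]], tab[["green"]],
              tab[["yellow"]]))
})

setMethod("show", "TwinSpotSet", function(object) {
  cat(sprintf("TwinSpotSet: %d twin spots (%d flagged as possible overlaps)\n",
              nrow(object@spots), sum(object@spots$flagged)))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d points, %d clusters, %d noise\n",
              nrow(object@points), nrow(object@clusters),
              sum(object@points$cluster == 0)))
})

setMethod("show", "CorneaReport", function(object) {
  cat(sprintf("CorneaReport %s [%s]\n", object@id, object@mode))
  cat(sprintf("  counts: red %d, green %d, yellow %d; green/red ratio: %s\n",
              object@counts[["red"]], object@counts[["green"]],
              object@counts[["yellow"]],
              if (object@ratioDefined) sprintf("%.3g", object@greenRedRatio)
              else "undefined"))
})

setMethod("show", "RegionSpec", function(object) {
  cat(sprintf(
    "RegionSpec: cornea R %g um, central zone %g um, peripheral band %g um, %d quadrants\n",
    object@corneaRadius, object@centralRadius, object@peripheralBand,
    as.integer(object@nQuadrants)))
})
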