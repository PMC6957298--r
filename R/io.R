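# File interfaces: TIFF images with pixel-scale sidecar metadata, CSV
# tables for each stage, YAML configs and JSON reports.

#' Write / read a two-channel panorama as TIFF
#'
#' One 16-bit TIFF per channel (red, green), plus a JSON sidecar
#' (\code{<baseName>_meta.json}) recording the physical pixel scale and
#' the field window in micrometers.
#'
#' @param channels list with \code{red}, \code{green}, \code{pixelScale}
#'   (see [renderChannels()]).
#' @param baseName path prefix; files \code{<baseName>_red.tif} and
#'   \code{<baseName>_green.tif} are written.
#' @return (invisibly) the written file names.
#' @export
writeChannelsTiff <- function(channels, baseName) {
  files <- c(red = paste0(baseName, "_red.tif"),
             green = paste0(baseName, "_green.tif"),
             meta = paste0(baseName, "_meta.json"))
  for (cc in c("red", "green")) {
    m <- channels[[cc]]
    m <- m / max(m, 1e-12)
    tiff::writeTIFF(t(m), files[[cc]], bits.per.sample = 16L,
                    compression = "none")
  }
  jsonlite::write_json(list(pixelScale_um = channels$pixelScale,
                            window_um = channels$window),
                       files[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' @rdname writeChannelsTiff
#' @param baseNameOrFiles path prefix used by [writeChannelsTiff()], or a
#'   named character vector (red, green) of file paths.
#' @param pixelScale um/px; when NULL, parsed from the TIFF description.
#' @export
readChannelsTiff <- function(baseNameOrFiles, pixelScale = NULL) {
  files <- if (length(baseNameOrFiles) >= 2) baseNameOrFiles
           else c(red = paste0(baseNameOrFiles, "_red.tif"),
                  green = paste0(baseNameOrFiles, "_green.tif"),
                  meta = paste0(baseNameOrFiles, "_meta.json"))
  red <- tiff::readTIFF(files[["red"]])
  green <- tiff::readTIFF(files[["green"]])
  window <- NULL
  if (is.null(pixelScale) && !is.na(files["meta"]) &&
      file.exists(files[["meta"]])) {
    meta <- jsonlite::read_json(files[["meta"]], simplifyVector = TRUE)
    pixelScale <- meta$pixelScale_um
    window <- meta$window_um
  }
  list(red = t(unclass(red)), green = t(unclass(green)),
       pixelScale = pixelScale, window = window)
}

#' Write a junction image as TIFF
#'
#' @param img matrix from [renderJunctions()].
#' @param file output path.
#' @return (invisibly) the path.
#' @export
writeJunctionTiff <- function(img, file) {
  tiff::writeTIFF(t(img / max(img, 1e-12)), file, bits.per.sample = 16L,
                  compression = "none")
  meta <- sub("\\.tiff?$", "_meta.json", file)
  jsonlite::write_json(list(pixelScale_um = attr(img, "pixelScale"),
                            window_um = attr(img, "window")),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Ground-truth cell table I/O
#'
#' @param mono a [SimulatedMonolayer-class].
#' @param file CSV path.
#' @return (invisibly) the path.
#' @export
writeCellTable <- function(mono, file) {
  utils::write.csv(cells(mono), file, row.names = FALSE)
  invisible(file)
}

#' Detection table I/O
#'
#' @param cellSet a [LabeledCellSet-class].
#' @param file CSV path.
#' @return (invisibly) the path.
#' @export
writeDetections <- function(cellSet, file) {
  utils::write.csv(detections(cellSet), file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeDetections
#' @param pixelScale um/px to record on the object.
#' @export
readDetections <- function(file, pixelScale = DEFAULT_PIXEL_SCALE) {
  det <- utils::read.csv(file, stringsAsFactors = FALSE)
  new("LabeledCellSet", detections = det, pixelScale = pixelScale,
      thresholds = c(red = NA_real_, green = NA_real_), source = file)
}

#' Twin-spot table output
#'
#' @param spotSet a [TwinSpotSet-class].
#' @param file CSV path.
#' @return (invisibly) the path.
#' @export
writeTwinSpots <- function(spotSet, file) {
  utils::write.csv(spots(spotSet), file, row.names = FALSE)
  invisible(file)
}

#' Cluster assignment output
#'
#' @param clusters output of [clusterByColor()] (or a single
#'   [ClusterAssignment-class]).
#' @param file CSV path.
#' @return (invisibly) the path.
#' @export
writeClusterAssignments <- function(clusters, file) {
  if (is(clusters, "ClusterAssignment")) {
    tab <- clusters@points
    tab$color <- NA_character_
  } else {
    cols <- setdiff(names(clusters), "percentInClusters")
    tab <- do.call(rbind, lapply(cols, function(cc) {
      p <- clusters[[cc]]@points
      if (nrow(p)) p$color <- cc else p$color <- character(0)
      p
    }))
  }
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' Cornea report JSON output
#'
#' @param report a [CorneaReport-class].
#' @param file JSON path.
#' @return (invisibly) the path.
#' @export
writeCorneaReport <- function(report, file) {
  x <- list(id = report@id, mode = report@mode,
            counts = as.list(report@counts),
            green_red_ratio = report@greenRedRatio,
            ratio_defined = report@ratioDefined,
            density = as.list(report@density),
            morpho = lapply(report@morpho, function(v)
              if (is.table(v)) as.list(v) else v),
            twin_spots = lapply(report@twinSpots, function(v)
              if (is.table(v)) as.list(v) else v),
            clusters = report@clusters,
            params = report@params, seed = report@seed)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}

#' Configuration YAML I/O
#'
#' @param config a [SimulationConfig-class].
#' @param file YAML path.
#' @return (invisibly) the path.
#' @export
writeConfigYaml <- function(config, file) {
  x <- list(corneaRadius = config@corneaRadius,
            targetDensity = config@targetDensity,
            nEvents = config@nEvents,
            segProbs = as.list(config@segProbs),
            expansionFold = as.list(config@expansionFold),
            cloneBaseMean = config@cloneBaseMean,
            dispersalSigma = as.list(config@dispersalSigma),
            eventMinSpacing = config@eventMinSpacing,
            mode = config@mode,
            pixelScale = config@pixelScale,
            junctionPixelScale = config@junctionPixelScale,
            spotSigma = config@spotSigma,
            noise = config@noise,
            lloydSteps = config@lloydSteps,
            seed = config@seed)
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname writeConfigYaml
#' @export
readConfigYaml <- function(file) {
  x <- yaml::read_yaml(file)
  for (nm in c("segProbs", "expansionFold", "dispersalSigma"))
    x[[nm]] <- unlist(x[[nm]])
  do.call(simulationConfig, x)
}
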