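#' Green/red cell ratio
#'
#' The headline clonal-expansion metric: count of green single-labeled
#' cells divided by count of red single-labeled cells. Undefined (flagged,
#' ratio NA) when there are no red cells; counts are always reported.
#'
#' @param cellSet a [LabeledCellSet-class] (or a data.frame of detections
#'   with a \code{class} column).
#' @return list: \code{ratio}, \code{nGreen}, \code{nRed}, \code{defined}.
#' @examples
#' det <- data.frame(id = 1:16, x_um = 0, y_um = 0, red_int = 0,
#'                   green_int = 0,
#'                   class = rep(c("green", "red"), c(12, 4)))
#' cs <- new("LabeledCellSet", detections = det, pixelScale = 3.02,
#'           thresholds = c(red = 0, green = 0), source = "example")
#' greenRedRatio(cs)$ratio  # 3
#' @export
greenRedRatio <- function(cellSet) {
  det <- if (is(cellSet, "LabeledCellSet")) cellSet@detections else cellSet
  nG <- sum(det$class == "green")
  nR <- sum(det$class == "red")
  list(ratio = if (nR > 0) nG / nR else NA_real_,
       nGreen = nG, nRed = nR, defined = nR > 0)
}

#' Fold change between a mutant and a control measurement
#'
#' @param mutant,control numeric measurements; \code{control} must be > 0.
#' @return list: \code{fold} (mutant/control) and \code{percentChange}
#'   (100 x (mutant - control)/control).
#' @examples
#' foldChange(4000, 2500)  # 1.6-fold, +60%
#' @export
foldChange <- function(mutant, control) {
  if (any(control <= 0)) stop("control must be > 0")
  list(fold = mutant / control,
       percentChange = 100 * (mutant - control) / control)
}

#' Summarize one cornea into a validated report
#'
#' Aggregates the stage outputs of a single cornea: labeled-cell counts and
#' the green/red ratio, regional densities and morphometrics from the
#' junction-image tessellation, the twin-spot summary and per-color cluster
#' summaries. Missing stages yield explicit NA fields.
#'
#' @param id cornea identifier.
#' @param cellSet a [LabeledCellSet-class] or NULL.
#' @param tess a [CellTessellation-class] or NULL.
#' @param spotSet a [TwinSpotSet-class] or NULL.
#' @param clusters output of [clusterByColor()] or NULL.
#' @param mode genotype mode label.
#' @param params list of parameter echoes to record.
#' @param seed the seed used for this cornea.
#' @param regionDensities optional named numeric (central, peripheral),
#'   cells/mm^2, from regional sampling.
#' @return a [CorneaReport-class].
#' @export
summarizeCornea <- function(id, cellSet = NULL, tess = NULL, spotSet = NULL,
                            clusters = NULL, mode = "WT-MADM",
                            params = list(), seed = NA_real_,
                            regionDensities = NULL) {
  counts <- c(red = 0, green = 0, yellow = 0)
  ratio <- NA_real_; defined <- FALSE
  if (!is.null(cellSet)) {
    det <- cellSet@detections
    counts <- c(red = sum(det$class == "red"),
                green = sum(det$class == "green"),
                yellow = sum(det$class == "yellow"))
    gr <- greenRedRatio(cellSet)
    ratio <- gr$ratio; defined <- gr$defined
  }
  dens <- c(central = NA_real_, peripheral = NA_real_, overall = NA_real_)
  morpho <- list()
  if (!is.null(tess) && nrow(tess@cells)) {
    dens[["overall"]] <- cellDensity(tess)
    morpho <- summarizeMorphometrics(morphometrics(tess))
  }
  if (!is.null(regionDensities)) {
    dens[names(regionDensities)] <- regionDensities
  }
  tw <- if (!is.null(spotSet)) twinSpotStats(spotSet) else list()
  clSummary <- list()
  if (!is.null(clusters)) {
    clSummary$percentInClusters <- clusters$percentInClusters
    clSummary$nClusters <- vapply(
      clusters[setdiff(names(clusters), "percentInClusters")],
      function(a) nrow(a@clusters), integer(1))
  }
  new("CorneaReport", id = as.character(id), mode = mode, counts = counts,
      greenRedRatio = ratio, ratioDefined = defined, density = dens,
      morpho = morpho, twinSpots = tw, clusters = clSummary,
      params = params, seed = as.numeric(seed))
}

#' Long-format batch table and group summaries over corneas
#'
#' @param reports list of [CorneaReport-class] objects.
#' @return list: \code{table} (one row per cornea x metric) and
#'   \code{groups} (mean, SEM and n per mode x metric).
#' @export
batchSummary <- function(reports) {
  rows <- lapply(reports, function(r) {
    metrics <- c(
      n_red = unname(r@counts[["red"]]),
      n_green = unname(r@counts[["green"]]),
      n_yellow = unname(r@counts[["yellow"]]),
      green_red_ratio = r@greenRedRatio,
      density_overall = unname(r@density[["overall"]]),
      density_central = unname(r@density[["central"]]),
      density_peripheral = unname(r@density[["peripheral"]]),
      twin_spots = if (length(r@twinSpots)) r@twinSpots$nSpots else NA_real_,
      pct_clusters_green = if (length(r@clusters))
        unname(r@clusters$percentInClusters[["green"]]) else NA_real_,
      pct_clusters_red = if (length(r@clusters))
        unname(r@clusters$percentInClusters[["red"]]) else NA_real_)
    data.frame(cornea = r@id, mode = r@mode, metric = names(metrics),
               value = unname(metrics), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  grp <- do.call(rbind, lapply(
    split(tab, list(tab$mode, tab$metric), drop = TRUE), function(s) {
      v <- s$value[is.finite(s$value)]
      data.frame(mode = s$mode[1], metric = s$metric[1],
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                       else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  rownames(grp) <- NULL
  list(table = tab, groups = grp)
}

#' Run the full pipeline on one simulated cornea
#'
#' simulate -> render -> detect -> twin spots -> cluster -> report. The
#' junction-segmentation stage is run on a regional field (rendering the
#' whole cornea at junction resolution is unnecessary for density
#' estimation and is skipped unless requested).
#'
#' @param config a [SimulationConfig-class] (e.g. from [madmPreset()]).
#' @param id cornea identifier for the report.
#' @param segmentField logical; also render and segment a central junction
#'   field to estimate density morphometrics.
#' @param outDir optional directory; when given, stage outputs are written
#'   (detections CSV, twin-spot CSV, cluster CSV, report JSON).
#' @return list with elements \code{monolayer}, \code{channels},
#'   \code{cells}, \code{twinSpots}, \code{clusters}, \code{tessellation}
#'   (or NULL) and \code{report}.
#' @export
runPipeline <- function(config, id = "cornea1", segmentField = FALSE,
                        outDir = NULL) {
  pos <- generatePositions(config)
  mono <- simulateMadm(config, pos)
  ch <- renderChannels(mono)
  cellsDet <- detectLabeledCells(ch)
  tw <- findTwinSpots(cellsDet)
  clus <- clusterByColor(cellsDet)
  tess <- NULL
  if (segmentField) {
    pts <- generatePositions(config, shape = "rect",
                             width = 400, height = 400)
    img <- renderJunctions(pts, config)
    tess <- detectCells(img)
  }
  modeLabel <- if (config@mode == "WT") "WT-MADM" else "GR-MADM"
  rep <- summarizeCornea(id, cellSet = cellsDet, tess = tess, spotSet = tw,
                         clusters = clus, mode = modeLabel,
                         params = list(pixelScale = config@pixelScale),
                         seed = config@seed)
  out <- list(monolayer = mono, channels = ch, cells = cellsDet,
              twinSpots = tw, clusters = clus, tessellation = tess,
              report = rep)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeDetections(cellsDet, file.path(outDir,
                                        paste0(id, "_cells.csv")))
    writeTwinSpots(tw, file.path(outDir, paste0(id, "_twinspots.csv")))
    writeClusterAssignments(clus, file.path(outDir,
                                            paste0(id, "_clusters.csv")))
    writeCorneaReport(rep, file.path(outDir, paste0(id, "_report.json")))
  }
  out
}
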