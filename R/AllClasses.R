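#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib corneaMADM, .registration = TRUE
NULL

#' Simulation configuration for a MADM-labeled corneal monolayer
#'
#' Holds every parameter of the generative model: monolayer geometry
#' (cornea disc radius and target cell density), recombination events
#' (number, segregation-mode probabilities, minimum event spacing),
#' genotype-specific clonal expansion and dispersal, rendering parameters
#' (pixel scales, spot width, noise model) and the RNG seed.
#'
#' @slot corneaRadius cornea disc radius in micrometers.
#' @slot targetDensity target cell density in cells per mm^2.
#' @slot nEvents number of recombination events to seed.
#' @slot segProbs named numeric of length 3 (\code{g2x}, \code{g2z},
#'   \code{g0g1}) summing to 1: probabilities of G2-X segregation (red/green
#'   sibling pair), G2-Z segregation (yellow/colorless pair) and a G0/G1
#'   event (single yellow cell).
#' @slot expansionFold named numeric (\code{WT}, \code{MUT}): expected
#'   single-labeled clone-size multiplier per genotype, relative to the
#'   wild-type baseline clone size \code{cloneBaseMean}.
#' @slot cloneBaseMean expected wild-type (fold 1) single-labeled clone size;
#'   clone sizes are drawn as \code{1 + Poisson(cloneBaseMean * fold - 1)} so
#'   the mean is exactly \code{cloneBaseMean * fold} with minimum 1.
#' @slot dispersalSigma named numeric (\code{WT}, \code{MUT}): per-division
#'   isotropic Gaussian displacement scale in micrometers.
#' @slot eventMinSpacing minimum distance in micrometers between the anchor
#'   positions of distinct recombination events.
#' @slot mode \code{"WT"} (WT-MADM: all labeled cells wild-type) or
#'   \code{"GR"} (GR-MADM: green cells homozygous mutant, red homozygous
#'   wild-type).
#' @slot pixelScale micrometers per pixel for two-channel panorama rendering;
#'   default 248/82 = 3.02439.
#' @slot junctionPixelScale micrometers per pixel for junction-label image
#'   rendering (junction images are acquired at higher magnification than
#'   panoramas).
#' @slot spotSigma Gaussian spot sigma in micrometers used when rendering
#'   labeled cells.
#' @slot noise list with elements \code{background} (fractional background
#'   level), \code{poisson} (logical, photon noise), \code{streaks} (logical,
#'   green radial bleed-through streak artifacts) and \code{nStreaks}.
#' @slot lloydSteps number of Lloyd relaxation steps applied after
#'   Poisson-disc sampling.
#' @slot seed integer RNG seed; every stage derives its stream from it.
#' @seealso [simulationConfig()], [madmPreset()]
#' @export
setClass("SimulationConfig", representation(
  corneaRadius = "numeric",
  targetDensity = "numeric",
  nEvents = "numeric",
  segProbs = "numeric",
  expansionFold = "numeric",
  cloneBaseMean = "numeric",
  dispersalSigma = "numeric",
  eventMinSpacing = "numeric",
  mode = "character",
  pixelScale = "numeric",
  junctionPixelScale = "numeric",
  spotSigma = "numeric",
  noise = "list",
  lloydSteps = "numeric",
  seed = "numeric"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@corneaRadius <= 0) msg <- c(msg, "corneaRadius must be > 0")
  if (object@targetDensity < 0) msg <- c(msg, "targetDensity must be >= 0")
  if (object@nEvents < 0) msg <- c(msg, "nEvents must be >= 0")
  if (length(object@segProbs) != 3 ||
      !all(c("g2x", "g2z", "g0g1") %in% names(object@segProbs)))
    msg <- c(msg, "segProbs must be named (g2x, g2z, g0g1)")
  else {
    if (any(object@segProbs < 0)) msg <- c(msg, "segProbs must be >= 0")
    if (abs(sum(object@segProbs) - 1) > 1e-9)
      msg <- c(msg, "segProbs must sum to 1")
  }
  if (!all(c("WT", "MUT") %in% names(object@expansionFold)))
    msg <- c(msg, "expansionFold must be named (WT, MUT)")
  else if (any(object@expansionFold < 0))
    msg <- c(msg, "expansionFold must be >= 0")
  if (any(object@cloneBaseMean * object@expansionFold < 1))
    msg <- c(msg, "cloneBaseMean * expansionFold must be >= 1 for every genotype")
  if (!all(c("WT", "MUT") %in% names(object@dispersalSigma)))
    msg <- c(msg, "dispersalSigma must be named (WT, MUT)")
  else if (any(object@dispersalSigma < 0))
    msg <- c(msg, "dispersalSigma must be >= 0")
  if (!object@mode %in% c("WT", "GR")) msg <- c(msg, "mode must be 'WT' or 'GR'")
  if (object@pixelScale <= 0) msg <- c(msg, "pixelScale must be > 0")
  if (object@junctionPixelScale <= 0) msg <- c(msg, "junctionPixelScale must be > 0")
  if (object@spotSigma <= 0) msg <- c(msg, "spotSigma must be > 0")
  if (!all(c("background", "poisson", "streaks") %in% names(object@noise)))
    msg <- c(msg, "noise must have elements background, poisson, streaks")
  if (object@lloydSteps < 0) msg <- c(msg, "lloydSteps must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground-truth MADM monolayer
#'
#' The output of [simulateMadm()]: one record per cell (background and
#' labeled), with color, clone, event and genotype bookkeeping, plus the
#' generating configuration.
#'
#' @slot cells data.frame with columns \code{id}, \code{x_um}, \code{y_um},
#'   \code{color} (red/green/yellow/colorless), \code{clone_id},
#'   \code{event_id}, \code{genotype} (WT/MUT/HET).
#' @slot config the [SimulationConfig-class] that generated it.
#' @slot provenance list (seed, generator version).
#' @export
setClass("SimulatedMonolayer", representation(
  cells = "data.frame",
  config = "SimulationConfig",
  provenance = "list"
))

setValidity("SimulatedMonolayer", function(object) {
  cl <- object@cells
  need <- c("id", "x_um", "y_um", "color", "clone_id", "event_id", "genotype")
  if (!all(need %in% names(cl)))
    return(paste("cells must have columns:", paste(need, collapse = ", ")))
  if (nrow(cl)) {
    single <- cl$color %in% c("red", "green")
    if (any(single & is.na(cl$event_id)))
      return("every red or green cell must carry an event_id")
    r <- sqrt((cl$x_um - 0)^2 + (cl$y_um - 0)^2)
    if (any(r > object@config@corneaRadius + 1e-6))
      return("all cells must lie inside the cornea disc")
    if (object@config@mode == "GR") {
      if (any(cl$color == "green" & cl$genotype != "MUT") ||
          any(cl$color == "red" & cl$genotype != "WT"))
        return("GR-MADM: green cells must be MUT and red cells WT")
    } else {
      if (any(cl$color %in% c("red", "green") & cl$genotype != "WT"))
        return("WT-MADM: all single-labeled cells must be WT")
    }
  }
  TRUE
})

#' Cell tessellation from a junction-label image
#'
#' Per-cell Dirichlet polygons and derived geometry produced by
#' [detectCells()] (or built directly from polygons with
#' [cellTessellationFromPolygons()]).
#'
#' @slot cells data.frame: \code{id}, \code{centroid_x_um},
#'   \code{centroid_y_um}, \code{area_um2}, \code{perimeter_um},
#'   \code{is_border}.
#' @slot polygons list of two-column matrices (vertex x/y in micrometers),
#'   one simple polygon per cell.
#' @slot neighbors list of integer vectors: ids of cells sharing a
#'   tessellation edge of length >= 1 px.
#' @slot pixelScale micrometers per pixel of the source image.
#' @slot window numeric length 4 (xmin, xmax, ymin, ymax) in micrometers.
#' @slot provenance character description of the source image.
#' @export
setClass("CellTessellation", representation(
  cells = "data.frame",
  polygons = "list",
  neighbors = "list",
  pixelScale = "numeric",
  window = "numeric",
  provenance = "character"
))

setValidity("CellTessellation", function(object) {
  cl <- object@cells
  need <- c("id", "centroid_x_um", "centroid_y_um", "area_um2",
            "perimeter_um", "is_border")
  if (!all(need %in% names(cl)))
    return(paste("cells must have columns:", paste(need, collapse = ", ")))
  if (length(object@polygons) != nrow(cl) || length(object@neighbors) != nrow(cl))
    return("polygons and neighbors must have one entry per cell")
  # neighbor symmetry
  for (i in seq_along(object@neighbors)) {
    for (j in object@neighbors[[i]]) {
      k <- match(j, cl$id)
      if (is.na(k) || !(cl$id[i] %in% object@neighbors[[k]]))
        return("neighbor relation must be symmetric")
    }
  }
  TRUE
})

#' Regional sampling specification
#'
#' Defines the central and peripheral sampling geometry of a corneal
#' flat-mount: a central disc and a peripheral annulus at the cornea-sclera
#' junction, each sampled at one site per tissue quadrant.
#'
#' @slot center numeric length 2, cornea center (micrometers).
#' @slot corneaRadius cornea radius, micrometers.
#' @slot centralRadius radius of the central zone, micrometers (default 1250).
#' @slot peripheralBand width of the peripheral annulus inside the cornea
#'   edge, micrometers (default 200).
#' @slot nQuadrants number of tissue quadrants (4).
#' @export
setClass("RegionSpec", representation(
  center = "numeric",
  corneaRadius = "numeric",
  centralRadius = "numeric",
  peripheralBand = "numeric",
  nQuadrants = "numeric"
))

setValidity("RegionSpec", function(object) {
  if (length(object@center) != 2) return("center must have length 2")
  if (object@corneaRadius <= 0) return("corneaRadius must be > 0")
  if (object@centralRadius <= 0 ||
      object@centralRadius >= object@corneaRadius - object@peripheralBand)
    return("need 0 < centralRadius < corneaRadius - peripheralBand")
  if (object@nQuadrants < 1) return("nQuadrants must be >= 1")
  TRUE
})

#' Detected labeled cells in a two-channel panorama
#'
#' @slot detections data.frame: \code{id}, \code{x_um}, \code{y_um},
#'   \code{red_int}, \code{green_int}, \code{class} (red/green/yellow).
#' @slot pixelScale micrometers per pixel of the source panorama.
#' @slot thresholds named numeric (red, green): the intensity thresholds the
#'   classification used.
#' @slot source character, source image id.
#' @export
setClass("LabeledCellSet", representation(
  detections = "data.frame",
  pixelScale = "numeric",
  thresholds = "numeric",
  source = "character"
))

setValidity("LabeledCellSet", function(object) {
  d <- object@detections
  need <- c("id", "x_um", "y_um", "red_int", "green_int", "class")
  if (!all(need %in% names(d)))
    return(paste("detections must have columns:", paste(need, collapse = ", ")))
  if (nrow(d) && !all(d$class %in% c("red", "green", "yellow")))
    return("class must be red, green or yellow")
  TRUE
})

#' Twin spots: grouped red+green single-labeled cells
#'
#' @slot spots data.frame: \code{spot_id}, \code{size}, \code{n_red},
#'   \code{n_green}, \code{centroid_x_um}, \code{centroid_y_um},
#'   \code{diameter_um}, \code{flagged} (possible overlap of two events).
#' @slot members list of integer vectors of member detection ids per spot.
#' @slot params list echo of the [twinSpotParams()] used.
#' @export
setClass("TwinSpotSet", representation(
  spots = "data.frame",
  members = "list",
  params = "list"
))

setValidity("TwinSpotSet", function(object) {
  s <- object@spots
  need <- c("spot_id", "size", "n_red", "n_green", "centroid_x_um",
            "centroid_y_um", "diameter_um", "flagged")
  if (!all(need %in% names(s)))
    return(paste("spots must have columns:", paste(need, collapse = ", ")))
  if (nrow(s)) {
    if (any(s$n_red < 1) || any(s$n_green < 1))
      return("every twin spot needs n_red >= 1 and n_green >= 1")
    if (any(s$size != s$n_red + s$n_green))
      return("size must equal n_red + n_green")
  }
  if (length(object@members) != nrow(s))
    return("members must have one entry per spot")
  TRUE
})

#' Density-based cluster assignment of labeled cells
#'
#' @slot points data.frame: \code{id}, \code{x_um}, \code{y_um},
#'   \code{cluster} (integer >= 1, or 0 for noise).
#' @slot clusters data.frame: \code{cluster}, \code{size},
#'   \code{centroid_x_um}, \code{centroid_y_um}.
#' @slot params list echo of the [clusteringParams()] used.
#' @export
setClass("ClusterAssignment", representation(
  points = "data.frame",
  clusters = "data.frame",
  params = "list"
))

setValidity("ClusterAssignment", function(object) {
  p <- object@points
  if (!all(c("id", "x_um", "y_um", "cluster") %in% names(p)))
    return("points must have columns id, x_um, y_um, cluster")
  if (nrow(object@clusters)) {
    if (any(object@clusters$size < 1))
      return("clusters must be non-empty")
    if (!setequal(object@clusters$cluster,
                  unique(object@points$cluster[object@points$cluster > 0])))
      return("cluster table must match point labels")
  }
  TRUE
})

#' Per-cornea quantification report
#'
#' @slot id cornea identifier.
#' @slot mode genotype mode label (e.g. "WT-MADM", "GR-MADM-CK", "GR-MADM-KO").
#' @slot counts named numeric (red, green, yellow).
#' @slot greenRedRatio numeric; NA when no red cells (undefined flag).
#' @slot ratioDefined logical.
#' @slot density named numeric (central, peripheral, overall), cells/mm^2;
#'   NA where not measured.
#' @slot morpho list of regional morphometric summaries.
#' @slot twinSpots list summary from [twinSpotStats()].
#' @slot clusters list of per-color cluster summaries.
#' @slot params list of parameter echoes.
#' @slot seed numeric seed used.
#' @export
setClass("CorneaReport", representation(
  id = "character",
  mode = "character",
  counts = "numeric",
  greenRedRatio = "numeric",
  ratioDefined = "logical",
  density = "numeric",
  morpho = "list",
  twinSpots = "list",
  clusters = "list",
  params = "list",
  seed = "numeric"
))
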